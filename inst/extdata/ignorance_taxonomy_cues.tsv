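pattern	category_ids	source
aim	question_answered	paper_table1
goal	question_answered	paper_table1
objective	question_answered	paper_table1
our study	question_answered	paper_table1
sought	question_answered	paper_table1
to determine	question_answered	paper_table1
could not find	full_unknown	paper_table1
do not know	full_unknown	paper_table1
elusive	full_unknown	paper_table1
not ... established	full_unknown	paper_table1
uncertain	full_unknown	paper_table1
still unclear	full_unknown	paper_table1
what	explicit_question	paper_table1
where	explicit_question	paper_table1
why	explicit_question	paper_table1
wondered	explicit_question	paper_table1
?	explicit_question	paper_table1
a good understanding	incomplete_evidence	paper_table1
believe	incomplete_evidence	paper_table1
evidence ... limited	incomplete_evidence	paper_table1
has been suggested	incomplete_evidence	paper_table1
hypothesis	incomplete_evidence	paper_table1
no studies	incomplete_evidence	paper_table1
possibly	incomplete_evidence	paper_table1
preliminary stage	incomplete_evidence	paper_table1
remains under investigation	incomplete_evidence	paper_table1
still being discovered	incomplete_evidence	paper_table1
support	incomplete_evidence	paper_table1
trend	incomplete_evidence	paper_table1
affect	superficial_relationship	paper_table1
associated	superficial_relationship	paper_table1
correlate	superficial_relationship	paper_table1
factor	superficial_relationship	paper_table1
influence	superficial_relationship	paper_table1
interact	superficial_relationship	paper_table1
link	superficial_relationship	paper_table1
pattern	superficial_relationship	paper_table1
tend	superficial_relationship	paper_table1
almost all	probable_understanding	paper_table1
assumed	probable_understanding	paper_table1
concluding	probable_understanding	paper_table1
evident	probable_understanding	paper_table1
it is clear	probable_understanding	paper_table1
most likely	probable_understanding	paper_table1
thus	probable_understanding	paper_table1
appeared to be	anomaly_curious	paper_table1
interestingly	anomaly_curious	paper_table1
noteworthy	anomaly_curious	paper_table1
surprisingly	anomaly_curious	paper_table1
cannot rule out	alternative_controversy	paper_table1
claims	alternative_controversy	paper_table1
has been challenged	alternative_controversy	paper_table1
whether	alternative_controversy	paper_table1
whilst	alternative_controversy	paper_table1
not feasible	difficult_task	paper_table1
remains ... challenge	difficult_task	paper_table1
variability	difficult_task	paper_table1
rarely able to	difficult_task	paper_table1
issue	problem_complication	paper_table1
error	problem_complication	paper_table1
insufficient	problem_complication	paper_table1
lack of reproducibility	problem_complication	paper_table1
publication bias	problem_complication	paper_table1
underestimated	problem_complication	paper_table1
additional research	future_work	paper_table1
are needed	future_work	paper_table1
continue to explore	future_work	paper_table1
further study	future_work	paper_table1
more ... studies	future_work	paper_table1
recommend	future_work	paper_table1
warrants	future_work	paper_table1
worthy of closer attention	future_work	paper_table1
allow	future_prediction	paper_table1
expect	future_prediction	paper_table1
if so	future_prediction,alternative_controversy	paper_table1
serve as a basis	future_prediction	paper_table1
will	future_prediction	paper_table1
call for action	important_consideration	paper_table1
cautious	important_consideration	paper_table1
crucial	important_consideration	paper_table1
emphasis	important_consideration	paper_table1
global problem	important_consideration	paper_table1
high on the agenda	important_consideration	paper_table1
necessary	important_consideration	paper_table1
relevant to note	important_consideration	paper_table1
vital	important_consideration	paper_table1
unknown	full_unknown	imported
lack of ... data	full_unknown	imported
no ... exist	incomplete_evidence	imported
reported	incomplete_evidence	imported
recent studies	incomplete_evidence	imported
contradictory	alternative_controversy	imported
owing to	problem_complication	imported
need to be	future_work	imported
need	future_work	imported
challenge	alternative_controversy,difficult_task	imported
imply	probable_understanding,superficial_relationship	imported
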