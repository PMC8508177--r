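id	name	level	parent	definition	knowledge_goal
levels_of_evidence	Levels of evidence	broad		Statements answering how much evidence exists and how confident we are in it, in increasing order.	Quantify and strengthen the evidence behind a claim
barriers	Barriers	broad		Statements of obstacles, complications, or multiple options that prevent research from moving forward and need to be overcome.	Remove the obstacle so research can proceed
future_opportunities	Future opportunities	broad		Statements of future needs such as future work or considerations.	Identify and pursue the next steps
question_answered	Question answered by this work	narrow	question_answered	A statement of a goal or objective of a study that is attempted or completed during the study.	Find the answer(s) in the article; determine if the question(s) is (are) fully answered in the article
full_unknown	Full unknown	narrow	levels_of_evidence	A statement that indicates something is not known (a lack of information), or information is presented for the first time and a significant amount of research is needed; not a statement about the absence of something.	Explore the unknown further to gain any insights
explicit_question	Explicit question	narrow	levels_of_evidence	An explicit statement of inquiry (with a question mark or question word such as how, where, what, why).	Find answers to the question and/or discover methodologies that will help answer the question
incomplete_evidence	Incomplete evidence	narrow	levels_of_evidence	A statement proposing a possible explanation on the basis of limited evidence as a starting point for further investigation, or a statement that information is limited, more research is needed or is ongoing, including limitations of the study design and execution.	Gather more evidence to support the claim or conduct more research to determine its validity; complete the partial picture
superficial_relationship	Superficial relationship	narrow	levels_of_evidence	A statement about a connection, link or association between at least two variables; connectedness between entities and/or interactions representing their relatedness or influence.	Confirm the connection between variables; determine the full underlying relationship
probable_understanding	Probable understanding	narrow	levels_of_evidence	A statement staking a claim to the most likely explanation, relationship, or phenomenon; assumes there is a good chance this understanding is correct.	Determine if the most likely option is correct or if another option is more feasible
anomaly_curious	Anomaly/curious finding	narrow	anomaly_curious	A statement of a surprising result, conclusion, observation or situation that the researchers were not expecting but are intrigued by.	Explore the surprising result further and determine if it is repeatable
alternative_controversy	Alternative options/controversy	narrow	barriers	An explicit statement of multiple choices, actions, approaches or methods that need to be experimentally determined, including an implied second option; or a statement of disagreement amongst researchers, lack of consensus, or contradictions.	Determine the correct or better option; resolve disagreements
difficult_task	Difficult task	narrow	barriers	A statement of something not easily done, accomplished, comprehended or solved; or a complicated thing with a multitude of underlying pieces; heterogeneity; excludes medical complications.	Create methods to study the complicated system and better understand its pieces
problem_complication	Problem/complication	narrow	barriers	A statement of issues, problems, mistakes or medical complications that are cause for anxiety and/or worry.	Determine the gravity of the concern and whether it must be dealt with before the next study
future_work	Future work	narrow	future_opportunities	A statement of extensions, next steps, directions, opportunities or considerations of the described work that may be implemented at some future time point; includes suggestions or proposals as to the next best course of action.	Determine the next course of action based on the proposal
future_prediction	Future prediction	narrow	future_opportunities	A statement of extrapolation of given data into the future and/or from past observations, without reference to next steps.	Run the simulation or experiment to determine if the prediction is correct
important_consideration	Important consideration	narrow	future_opportunities	A statement calling for attention, including an action or information needed immediately; critical, urgently needed, or absolutely necessary.	Take the urgent action or distribute the knowledge as soon as possible
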