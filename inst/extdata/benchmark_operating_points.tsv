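group	label	mode	precision	recall	f1
embedding	GoogleNews	strict	0.9679	0.9263	0.9466
embedding	CommonCrawl	strict	0.9697	0.9401	0.9547
embedding	MIMIC-word2vec	strict	0.9669	0.9341	0.9502
embedding	MIMIC-fastText	strict	0.9631	0.9380	0.9504
embedding	MADE	strict	0.9662	0.9158	0.9403
embedding	GoogleNews	relax	0.9783	0.9362	0.9567
embedding	CommonCrawl	relax	0.9797	0.9498	0.9646
embedding	MIMIC-word2vec	relax	0.9774	0.9443	0.9606
embedding	MIMIC-fastText	relax	0.9758	0.9504	0.9629
embedding	MADE	relax	0.9782	0.9271	0.9520
model	base-source-only	strict	0.8883	0.8274	0.8568
model	lexical-source-only	strict	0.8767	0.8509	0.8636
model	lexical-knowledge-source-only	strict	0.8767	0.8706	0.8736
model	lexical-knowledge-finetuned	strict	0.9474	0.9109	0.9288
model	lexical-knowledge-target-only	strict	0.9408	0.8992	0.9195
model	lexical-knowledge-merged	strict	0.9352	0.9163	0.9257
model	base-source-only	relax	0.9288	0.8651	0.8958
model	lexical-source-only	relax	0.9314	0.9041	0.9175
model	lexical-knowledge-source-only	relax	0.9229	0.9166	0.9197
model	lexical-knowledge-finetuned	relax	0.9776	0.9400	0.9584
model	lexical-knowledge-target-only	relax	0.9705	0.9277	0.9486
model	lexical-knowledge-merged	relax	0.9681	0.9484	0.9582
category	DATE	strict	0.9807	0.9770	0.9789
category	AGE	strict	0.9861	0.8659	0.9221
category	ID	strict	0.9173	0.8905	0.9037
category	NAME	strict	0.9029	0.8807	0.8917
category	PHONE	strict	0.9048	0.8085	0.8539
category	ZIP	strict	0.7500	0.7500	0.7500
category	INSTITUTE	strict	0.7500	0.5042	0.6030
category	CITY	strict	0.9048	0.4222	0.5758
category	STREET	strict	0.5500	0.5238	0.5366
category	WEB	strict	0.0000	0.0000	0.0000
category	DATE	relax	0.9850	0.9813	0.9831
category	AGE	relax	0.9861	0.8659	0.9221
category	ID	relax	0.9624	0.9343	0.9481
category	NAME	relax	0.9694	0.9455	0.9573
category	PHONE	relax	0.9762	0.8723	0.9213
category	ZIP	relax	0.9000	0.9000	0.9000
category	INSTITUTE	relax	0.9375	0.6303	0.7538
category	CITY	relax	1.0000	0.4667	0.6364
category	STREET	relax	0.8500	0.8095	0.8293
category	WEB	relax	0.0000	0.0000	0.0000
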