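prefix,category
401,Essential hypertension
402,Hypertension with complications
410,Acute myocardial infarction
414,Coronary atherosclerosis
430,Acute cerebrovascular disease
435,Transient cerebral ischemia
438,Late effects of cerebrovascular disease
296,Mood disorders
300,Anxiety disorders
332,Parkinson disease
466,Acute bronchitis
599,Urinary tract infections
715,Osteoarthritis
721,Spondylosis
4,Other circulatory disease
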