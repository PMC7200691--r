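phecode,description,exclude_low,exclude_high,sex_specific
401,hypertension,401,405.99,none
401.1,essential hypertension,401,405.99,none
401.2,secondary hypertension,401,405.99,none
250,diabetes mellitus,249,250.99,none
250.1,type 1 diabetes,249,250.99,none
250.2,type 2 diabetes,249,250.99,none
272,disorders of lipoid metabolism,272,272.99,none
272.1,hyperlipidemia,272,272.99,none
415,pulmonary heart disease,415,417.99,none
416,cardiomegaly,415,417.99,none
416.2,hypertrophic cardiomyopathy,415,417.99,none
417,other pulmonary circulation disease,415,417.99,none
185,prostate cancer,185,187.99,male
174,breast cancer,174,175.99,female
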