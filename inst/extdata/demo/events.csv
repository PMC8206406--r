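member_id,date,kind,system,code,value
M001,2010-06-15,diagnosis,ICD9,250.00,
M001,2011-02-10,lab_result,LOINC,4548-4,7.2
M002,2012-05-20,diagnosis,ICD10,I10,
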