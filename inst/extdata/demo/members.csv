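member_id,sex,birth_year
M001,male,1955
M002,female,1970
M003,female,2001
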