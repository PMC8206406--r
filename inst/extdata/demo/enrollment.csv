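member_id,start,end
M001,2010-01-01,2015-12-31
M002,2011-03-15,2016-02-29
M003,2012-01-01,2014-06-30
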