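compound_id	ko_id
C00037	K00001
C00041	K00002
C00041	K00003
C00186	K09999
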