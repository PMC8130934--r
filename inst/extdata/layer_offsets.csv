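layer,offset_deg,format_version
DG-GC,-160,1.0
hilus,-170,1.0
CA3a,-30,1.0
CA3b,-80,1.0
CA3c,-180,1.0
CA2,-10,1.0
CA1-SLM,-180,1.0
CA1-SR,-60,1.0
CA1-SP,0,1.0
EC1,-180,1.0
EC2,0,1.0
EC3,0,1.0
EC4,0,1.0
EC5,0,1.0
EC6,0,1.0
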