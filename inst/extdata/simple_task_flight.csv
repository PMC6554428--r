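subject,trials,gates_passed,boundary_crossings,total_flight_time_min
Sub5,10,9,0,4.8
Sub6,10,10,0,3.8
Sub7,10,10,0,4.2
Sub8,10,9,1,5.2
Sub9,10,8,1,5.1
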