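subject,trials,successes,half_successes,gates_passed,boundary_crossings,total_flight_time_min
Sub5,20,16,4,36,0,27.4
Sub6,20,19,1,39,0,20.7
Sub7,20,19,0,38,1,22.1
Sub8,20,16,1,33,3,30.0
Sub9,20,12,3,27,5,34.0
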