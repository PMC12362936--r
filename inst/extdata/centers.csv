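# Center rosters per phase of the dummy-run exercise. Phase 1 (independent
# delineation): 10 centers contoured; phase 2 (plan review on standardized
# volumes): 9 centers plus the coordinating center M submitted plans.
# ptv_eval_case4: whether the center planned Case4 on PTV-EVAL (PTV minus
# OARs) for all targets ("all"), only for PTV3 ("ptv3"), or not ("none").
center_id,phase1,phase2,ptv_eval_case4
A,TRUE,TRUE,none
B,FALSE,TRUE,none
C,TRUE,TRUE,none
D,TRUE,FALSE,none
E,TRUE,TRUE,none
F,TRUE,TRUE,none
G,TRUE,FALSE,none
H,TRUE,TRUE,none
I,FALSE,TRUE,all
J,TRUE,FALSE,none
K,TRUE,TRUE,all
L,TRUE,TRUE,ptv3
M,FALSE,TRUE,ptv3
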