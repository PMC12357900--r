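k_syn_A: 0.5
k_syn_C: 0.25
k_syn_RelB: 0.5
k_deg_A: 0.02
k_deg_C: 0.02
k_deg_B: 0.1
k0_Ia: 0.2
g_Ia: 30.0
k0_Ie: 2.0
g_Ie: 1.0
k0_Id: 0.0005
g_Id: 1.0
h: 6.0
K_tx: 5.0
kb_Ia_A: 1.0
kb_Ia_C: 0.05
kb_Ie_A: 2.0
kb_Ie_C: 6.0
kb_Id_A: 0.0005
kb_Id_C: 1.0
ku_Ia_A: 0.005
ku_Ia_C: 0.005
ku_Ie_A: 0.005
ku_Ie_C: 0.005
ku_Id_A: 0.005
ku_Id_C: 0.005
d0_Ia: 0.01
d0_Ie: 0.01
d0_Id: 0.03
d_ikk_Ia: 200.0
d_ikk_Ie: 300.0
k_proc: 0.02
k_syn_NIK: 0.1
k_deg_NIK: 0.1
k_in_A: 0.05
k_out_A: 0.02
k_in_C: 0.05
k_out_C: 0.02
b: 0.0005
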