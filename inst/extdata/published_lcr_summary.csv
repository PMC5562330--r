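# Ensemble LCR statistics at three SR Ca pumping rates (Pup, mM/s), from a
# published stochastic sinoatrial-node cell simulation study: LCR counts and
# total signal masses per class in one representative cycle. Total signal
# mass unit: nmol*ms x 1e-10.
pup_mM_s,count_all,count_complex,count_simple,total_mass_all,total_mass_complex,total_mass_simple
24,443,195,248,101,99.8,1.45
12,551,243,308,64.3,61.8,2.50
4,1978,210,1768,30.7,25.8,4.90
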