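pft,height_class,light_class,h0,h1,form_factor,rho,d_max,crown_d_ratio,crown_frac,pmax,alpha,lai_tree,r_m,r_g,m_base,ms0,ms1,m_stress,msen,d_fall,p_fall,n_seed,i_seed
1,>33,tolerant,160,50,0.52,0.6,1.7,20,0.35,5.14,0.05,3.3,0.0932,0.25,0.005,0.06,25,0.3,0.035,0.3,0.3,8,0.01
2,16-33,tolerant,120,28,0.5,0.55,0.66,20,0.35,3.23,0.05,3.3,0.0932,0.25,0.025,0.06,25,0.3,0.05,0.3,0.3,41,0.01
3,16-33,intermediate,120,28,0.5,0.5,0.76,20,0.35,4.07,0.05,3.3,0.0932,0.25,0.026,0.06,25,0.3,0.05,0.3,0.3,8,0.04
4,16-33,intolerant,130,28,0.45,0.4,0.66,20,0.35,6.49,0.05,3,0.0932,0.25,0.07,0.06,25,0.3,0.05,0.3,0.3,10,0.1
5,<16,tolerant,80,14,0.5,0.55,0.38,20,0.35,3.23,0.05,3.3,0.0932,0.25,0.045,0.06,25,0.3,0.05,0.3,0.3,14,0.01
6,<16,intolerant,90,14,0.4,0.3,0.28,20,0.35,6.5,0.05,2.4,0.0932,0.25,0.08,0.06,25,0.3,0.05,0.3,0.3,12,0.12
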