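reaction,dE_elec,dG_vrt,ddG_solv_cpcma,ddG_solv_smd,ddG_solv_ccsa,dG_sol_cpcma,dG_sol_smd,dG_sol_ccsa,dG_sol_exp
PhCOOH + piperidine -> PhCOO- + piperidineH+,111.95,0.83,-104.54,-111.07,-109.77,8.2,1.7,3.0,1.8
PhCOOH + MeOH -> PhCOO- + MeOH2+,160.57,-0.86,-115.26,-117.53,-130.59,44.4,42.2,29.1,25.0
PhCOOH + PhCOOH -> PhCOO- + PhCOOH2+,142.31,-1.04,-97.18,-100.05,-108.89,44.1,41.2,32.4,28.2
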