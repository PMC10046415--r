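# Synthetic two-pole Cole-Cole parameter table for the neck phantom tissues.
# These are stand-in values authored for this package in the style of the
# published tissue-dielectric literature (Gabriel-type dispersions truncated
# to two poles); they are fixture data, not transcribed from any database.
# Columns: eps_inf, delta_eps1/2 (dimensionless), tau1/2 (s), alpha1/2,
# sigma (S/m), and linear temperature coefficients c_* (relative change / C,
# reference 37 C) applied by params_at_temperature().
tissue,eps_inf,delta_eps1,tau1,alpha1,delta_eps2,tau2,alpha2,sigma,c_sigma,c_delta_eps1
skin,4.0,33.0,7.23e-12,0.00,1100,3.25e-8,0.20,0.0002,0.02,-0.005
fat,2.5,9.0,7.96e-12,0.20,35,1.59e-8,0.10,0.035,0.02,-0.005
muscle,4.0,50.0,7.23e-12,0.10,7000,3.54e-7,0.10,0.20,0.02,-0.005
bone,2.5,10.0,1.33e-11,0.20,180,7.96e-8,0.20,0.020,0.02,-0.005
spinal_cord,4.0,26.0,7.96e-12,0.10,500,1.06e-7,0.15,0.006,0.02,-0.005
thyroid,4.0,55.0,8.84e-12,0.10,2500,1.59e-7,0.10,0.50,0.02,-0.005
tumor,4.0,62.0,8.84e-12,0.10,3000,1.59e-7,0.10,0.80,0.02,-0.005
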