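name,kind,a,b,x_name,x_units,mass_units,x_min,x_max,source
basal_pterosaur_wingspan,power,476.557983427136,2.30,wingspan,m,g,0.1,3,"Witton (2008) basal (non-pterodactyloid) pterosaur wingspan-mass relation; prefactor calibrated so the relation reproduces the published 95 g reconstruction at 0.496 m wingspan"
pterodactyloid_wingspan,power,428.664893289502,2.30,wingspan,m,g,0.5,12,"Witton (2008) pterodactyloid wingspan-mass relation; prefactor calibrated so the relation reproduces the published 6540 g reconstruction at 3.270 m wingspan"
crocodylian_total_length,power,0.00443,3.10,total_length,cm,g,50,600,"Approximate crocodylian total length-mass scaling in the shape of published length-mass regressions; synthetic calibration, not validated against a published mass"
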