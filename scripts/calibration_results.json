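{"blocking_coefficients":{"a1":24.1509525466188,"a2":7.97569924345617e-11},"blocking_probes":{"seed":[1,1,1,1,1,1,1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2,2,2,2,2,2,2,3,3,3,3,3,3,3,3,3,3,3,3,3,3],"theta":[0.0199990331927859,0.0399980663855718,0.0599970995783577,0.0799961327711436,0.0999951659639295,0.119994199156715,0.139993232349501,0.159992265542287,0.179991298735073,0.199990331927859,0.219989365120645,0.239988398313431,0.259987431506217,0.279986464699003,0.0199990331927859,0.0399980663855718,0.0599970995783577,0.0799961327711436,0.0999951659639295,0.119994199156715,0.139993232349501,0.159992265542287,0.179991298735073,0.199990331927859,0.219989365120645,0.239988398313431,0.259987431506217,0.279986464699003,0.0199990331927859,0.0399980663855718,0.0599970995783577,0.0799961327711436,0.0999951659639295,0.119994199156715,0.139993232349501,0.159992265542287,0.179991298735073,0.199990331927859,0.219989365120645,0.239988398313431,0.259987431506217,0.279986464699003],"B":[0.57333325,0.29928375,0.14051875,0.06501025,0.032618,0.01724,0.00938475,0.0052845,0.00300825,0.00178075,0.0009485,0.0005315,0.00026925,0.00012,0.57563675,0.30369075,0.14529375,0.06872925,0.035353,0.01842875,0.01040775,0.00603625,0.003417,0.001918,0.00107925,0.00059825,0.00029275,0.000135,0.58015575,0.3046045,0.14170725,0.0682165,0.03321425,0.01706425,0.009543,0.00532825,0.00309725,0.001716,0.00089225,0.0004745,0.0002485,0.00010525]},"spt_coefficients":{"a1":23.7018697178146,"a2":11.3509348589073},"jamming_vs_hstar":{"h_star_nm":[0,0.1,0.2,0.3,0.45,0.6],"theta_J":[0.368890120350358,0.332051389004436,0.302467077317383,0.275096199453854,0.245802658238004,0.225059744767403]},"phi0_prefactor":0.58,"predicted_theta_mx":[0.362560280349276,0.362560280349276,0.368890120350358,0.368890120350358],"target_theta_mx":[0.35,0.37,0.4,0.43]}
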