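# Wild-type GV-arrest parameter set; time unit minutes, concentrations
# dimensionless.
Va1CDK = 0.015
Va2CDK = 1.5
Vi1CDK = 0.015
Vi2CDK = 0.3
VaCdh1 = 1.5
ViCdh1 = 6
JCdh1 = 0.15
Cdh1T = 1
VaWee = 0.375
ViWee = 1.5
Jwee = 0.01
Wee1T = 1
Va25 = 1.5
Vi25 = 0.375
J25 = 0.01
ksc25 = 0.015
kd1c25 = 0.015
kd2c25 = 0.15
ksCycB = 0.015
kd1CycB = 0.015
kd2CycB = 0.075
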