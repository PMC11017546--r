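category,code
URTI,J00
URTI,J01
URTI,J01.0
URTI,J01.00
URTI,J01.01
URTI,J01.1
URTI,J01.10
URTI,J01.11
URTI,J01.2
URTI,J01.20
URTI,J01.21
URTI,J01.3
URTI,J01.30
URTI,J01.31
URTI,J01.4
URTI,J01.40
URTI,J01.41
URTI,J01.8
URTI,J01.80
URTI,J01.81
URTI,J01.9
URTI,J01.90
URTI,J01.91
URTI,J02.0
URTI,J02.8
URTI,J02.9
URTI,J03.00
URTI,J03.01
URTI,J03.80
URTI,J03.9
URTI,J03.90
URTI,J03.91
URTI,J04
URTI,J04.0
URTI,J04.1
URTI,J04.10
URTI,J04.11
URTI,J04.2
URTI,J04.3
URTI,J04.30
URTI,J04.31
URTI,J05
URTI,J05.0
URTI,J05.1
URTI,J05.10
URTI,J05.11
URTI,J06
URTI,J06.0
URTI,J06.9
URTI,J09.X2
URTI,J09.X3
URTI,J09.X9
URTI,J10
URTI,J10.0
URTI,J10.00
URTI,J10.01
URTI,J10.08
URTI,J10.1
URTI,J10.2
URTI,J10.8
URTI,J10.81
URTI,J10.82
URTI,J10.83
URTI,J10.89
URTI,J11
URTI,J11.0
URTI,J11.00
URTI,J11.08
URTI,J11.1
URTI,J11.2
URTI,J11.8
URTI,J11.81
URTI,J11.82
URTI,J11.83
URTI,J11.89
URTI,J21.0
URTI,J21.8
URTI,J21.9
URTI,H65
URTI,H66
URTI,H66.9
LRTI,J20
LRTI,J20.0
LRTI,J20.1
LRTI,J20.2
LRTI,J20.3
LRTI,J20.4
LRTI,J20.5
LRTI,J20.6
LRTI,J20.7
LRTI,J20.8
LRTI,J20.9
LRTI,J21
LRTI,J21.0
LRTI,J21.1
LRTI,J21.8
LRTI,J21.9
LRTI,J09.X1
LRTI,J09.X2
LRTI,A37
LRTI,A37.00
LRTI,A22.1
LRTI,A37.01
LRTI,A37.10
LRTI,A37.11
LRTI,A37.80
LRTI,A37.81
LRTI,A37.90
LRTI,A37.91
LRTI,A48.1
LRTI,B25.0
LRTI,J12
LRTI,J12.0
LRTI,J12.1
LRTI,J12.2
LRTI,J12.3
LRTI,J12.8
LRTI,J12.81
LRTI,J12.82
LRTI,J12.89
LRTI,J12.9
LRTI,J13
LRTI,J14
LRTI,J15
LRTI,J15.0
LRTI,J15.01
LRTI,J15.1
LRTI,J15.2
LRTI,J15.20
LRTI,J15.21
LRTI,J15.211
LRTI,J15.212
LRTI,J15.29
LRTI,J15.3
LRTI,J15.4
LRTI,J15.5
LRTI,J15.6
LRTI,J15.7
LRTI,J15.8
LRTI,J15.9
LRTI,J16
LRTI,J16.0
LRTI,J16.8
LRTI,J17
LRTI,J18
LRTI,J18.0
LRTI,J18.1
LRTI,J18.2
LRTI,J18.8
LRTI,J18.9
LRTI,J18
LRTI,J21
LRTI,J20.9
LRTI,R05.1
LRTI,R05.2
asthma,J44.0
asthma,J44.1
asthma,J44.9
asthma,J45
asthma,J45.2
asthma,J45.20
asthma,J45.21
asthma,J45.22
asthma,J45.3
asthma,J45.30
asthma,J45.31
asthma,J45.32
asthma,J45.4
asthma,J45.40
asthma,J45.41
asthma,J45.42
asthma,J45.5
asthma,J45.50
asthma,J45.51
asthma,J45.52
asthma,J45.9
asthma,J45.90
asthma,J45.901
asthma,J45.902
asthma,J45.909
asthma,J45.99
asthma,J45.990
asthma,J45.991
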