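time_s,concentration,compound
0,50981380107595.086,IBAP_synthetic
60,47279944961068.969,IBAP_synthetic
120,43791662030882.758,IBAP_synthetic
180,40945229496550.094,IBAP_synthetic
240,39430589519715.922,IBAP_synthetic
300,37044376475209.797,IBAP_synthetic
360,34187282537260.598,IBAP_synthetic
420,31611191049947.438,IBAP_synthetic
480,28975376594071.066,IBAP_synthetic
540,27205154569814.488,IBAP_synthetic
600,25211138178071.766,IBAP_synthetic
660,24655210719896.352,IBAP_synthetic
720,23269483463242.129,IBAP_synthetic
780,21568853179523.414,IBAP_synthetic
840,18817759461109.648,IBAP_synthetic
900,18769029164740.387,IBAP_synthetic
0,58882721058401.727,CyHex_synthetic
60,57157349435032.914,CyHex_synthetic
120,51789409000797.875,CyHex_synthetic
180,48504627109275.734,CyHex_synthetic
240,48777144631327.734,CyHex_synthetic
300,45302310245193.539,CyHex_synthetic
360,43400729047334.656,CyHex_synthetic
420,39962654406034.5,CyHex_synthetic
480,38195809697596.938,CyHex_synthetic
540,34691497872016.875,CyHex_synthetic
600,33702797457678.367,CyHex_synthetic
660,32337165091790.613,CyHex_synthetic
720,28904412537128.969,CyHex_synthetic
780,28374655674163.996,CyHex_synthetic
840,26087900077523.621,CyHex_synthetic
900,25187266099356.547,CyHex_synthetic
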