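guest,N,E_complex,E_host,E_guest_aggregate
benzene,1,-513.0,-400.0,-100.0
benzene,2,-621.4,-400.0,-200.0
benzene,4,-826.4,-400.0,-400.0
anthracene,1,-670.0,-400.0,-250.0
anthracene,2,-919.4,-400.0,-500.0
salicylic_acid,1,-610.3,-400.0,-180.0
salicylic_acid,2,-790.0,-400.0,-360.0
salicylic_acid,4,-1167.9,-400.0,-720.0
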