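model,loglik,n_params,n_obs,bic_printed,aic_printed
RUM based MNL,-2765.470,23,3475,5718.467,5576.940
RUM based mixed MNL,-2759.650,24,3475,5714.980,5567.300
RRM based MNL,-2709.500,35,3475,5704.367,5489.000
RRM based mixed MNL,-2688.781,32,3475,5638.470,5441.563
RUM based Latent MNL with two segments,-2734.217,20,3475,5631.500,5508.434
RRM based Latent MNL with two segments,-2693.295,23,3475,5574.118,5432.591
RRM based Latent MNL with three segments,-2665.158,26,3475,5542.304,5382.316
LCMHS two segments (1 RUM-1 RRM),-2729.685,20,3475,5622.438,5499.371
LCMHS three segments (2 RUM-1 RRM),-2601.792,36,3475,5497.104,5275.583
LCMHS three segments (1 RUM-2 RRM),-2647.804,29,3475,5532.055,5353.608
LCMHS four segments (2 RUM-2 RRM),-2559.369,42,3475,5461.178,5202.738
LCMHS four segments (1 RUM-3 RRM),-2566.263,33,3475,5401.587,5198.526
LCMHS four segments (3 RUM-1 RRM),-2624.438,34,3475,5526.090,5316.876
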