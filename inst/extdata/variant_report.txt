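variant arbitration against targets: proposed=680760, v2=680832
exact match found: FALSE
best flags: conv_bias=off-before-norm; norm_affine=off; dsconv_style_in_feature_blocks=grouped-plus-pointwise; s1_third_branch_groups=16; bottleneck_chain=collapsed; skip_fusion=concatenate; final_upsample=x4-from-quarter; dilation_mapping=offset-by-one
  proposed: counted 680763, target 680760, delta +3
  v2: counted 680835, target 680832, delta +3
per-block breakdown of best candidate (proposed reading):
  stage1                13247
  stage2_inputs           792
  stage2_trunk          64512
  bottlenecks          131520
  feature_s1            36800
  feature_s2           114560
  feature_d            286464
  ppm                   18432
  fusion                    0
  classify              14436
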