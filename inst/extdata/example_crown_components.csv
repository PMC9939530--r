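tree,total_leaf_volume_m3,total_wood_volume_m3,crown_volume_m3,gf_vol_reported
crepe_myrtle,0.018,0.014,2.15,0.985
sakura,0.186,0.063,5.34,0.953
magnolia,0.051,0.019,2.18,0.968
rubber,1.71,0.560,86.17,0.973
ginkgo,0.52,0.101,14.86,0.958
plot_average,1.75,0.63,79.47,0.970
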