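comparison_id,figure,group,k,n,printed_percent,expected_sig
overall_electrical,Fig1h,sparse_cluster,44,134,,
elec_by_chem,Fig2b,chemically_connected,11,34,32.4,NS
elec_by_chem,Fig2b,not_chemically_connected,33,100,33.0,NS
chem_by_elec,Fig2c,electrically_coupled,11,44,25.0,NS
chem_by_elec,Fig2c,not_electrically_coupled,23,90,25.6,NS
egfp_control_electrical,Fig3f,sparse_cluster,9,31,29.0,
egfp_control_electrical,Fig3f,non_lineage,6,60,10.0,
egfp_control_chemical,Fig3g,sparse_cluster,9,31,29.0,
egfp_control_chemical,Fig3g,non_lineage,16,60,26.7,
lineage_electrical,Fig4i,sparse_cluster,27,80,33.8,p<0.001
lineage_electrical,Fig4i,non_lineage,59,462,12.8,p<0.001
lineage_electrical_dense,Fig4i,dense_dense,15,115,13.0,
lineage_chemical,Fig4j,sparse_cluster,19,80,23.8,
lineage_chemical,Fig4j,non_lineage,147,462,31.8,
lineage_chemical_dense,Fig4j,dense_dense,26,115,22.6,
subtype_nonFS_electrical,Fig6a,sparse_cluster,49,79,62.0,
subtype_nonFS_electrical,Fig6a,non_lineage,33,166,19.9,
subtype_FS_electrical,Fig6b,sparse_cluster,20,52,38.5,
subtype_FS_electrical,Fig6b,non_lineage,21,117,17.9,
distance_lt20_nonlineage,Fig6d,non_lineage_lt20um,4,7,57.1,
distance_gt150_nonlineage,Fig6d,non_lineage_gt150um,3,67,4.5,
age_P7_P10_electrical,Fig7a,sparse_cluster,4,21,19.0,
age_P7_P10_electrical,Fig7a,non_lineage,16,131,12.2,
coordinated_output,Fig8h,coupled_sparse,14,35,40.0,
coordinated_output,Fig8h,noncoupled_sparse,14,95,14.7,
coordinated_output,Fig8h,coupled_nonlineage,1,15,6.7,
coordinated_output,Fig8h,noncoupled_nonlineage,10,107,9.3,
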