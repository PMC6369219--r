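name,hemisphere,lobe,cortical
L_precentral_gyrus,left,frontal,TRUE
L_superior_frontal_gyrus_medial,left,frontal,TRUE
L_superior_frontal_gyrus_lateral,left,frontal,TRUE
L_middle_frontal_gyrus_anterior,left,frontal,TRUE
L_middle_frontal_gyrus_posterior,left,frontal,TRUE
L_inferior_frontal_gyrus_opercularis,left,frontal,TRUE
L_inferior_frontal_gyrus_triangularis,left,frontal,TRUE
L_inferior_frontal_gyrus_orbitalis,left,frontal,TRUE
L_gyrus_rectus,left,frontal,TRUE
L_medial_orbital_gyrus,left,frontal,TRUE
L_lateral_orbital_gyrus,left,frontal,TRUE
L_anterior_orbital_gyrus,left,frontal,TRUE
L_posterior_orbital_gyrus,left,frontal,TRUE
L_frontal_operculum,left,frontal,TRUE
L_frontal_pole,left,frontal,TRUE
L_supplementary_motor_area,left,frontal,TRUE
L_anterior_cingulate_gyrus,left,frontal,TRUE
L_middle_cingulate_gyrus,left,frontal,TRUE
L_paracentral_lobule_anterior,left,frontal,TRUE
L_precentral_gyrus_medial,left,frontal,TRUE
L_olfactory_cortex,left,frontal,TRUE
L_frontomarginal_gyrus,left,frontal,TRUE
L_temporal_pole,left,temporal,TRUE
L_superior_temporal_gyrus_anterior,left,temporal,TRUE
L_superior_temporal_gyrus_posterior,left,temporal,TRUE
L_middle_temporal_gyrus_anterior,left,temporal,TRUE
L_middle_temporal_gyrus_posterior,left,temporal,TRUE
L_inferior_temporal_gyrus,left,temporal,TRUE
L_fusiform_gyrus_anterior,left,temporal,TRUE
L_fusiform_gyrus_posterior,left,temporal,TRUE
L_parahippocampal_gyrus,left,temporal,TRUE
L_planum_polare,left,temporal,TRUE
L_planum_temporale,left,temporal,TRUE
L_heschls_gyrus,left,temporal,TRUE
L_postcentral_gyrus,left,parietal,TRUE
L_superior_parietal_lobule,left,parietal,TRUE
L_supramarginal_gyrus,left,parietal,TRUE
L_angular_gyrus,left,parietal,TRUE
L_precuneus,left,parietal,TRUE
L_posterior_cingulate_gyrus,left,parietal,TRUE
L_paracentral_lobule_posterior,left,parietal,TRUE
L_parietal_operculum,left,parietal,TRUE
L_intraparietal_cortex,left,parietal,TRUE
L_occipital_pole,left,occipital,TRUE
L_calcarine_cortex,left,occipital,TRUE
L_cuneus,left,occipital,TRUE
L_lingual_gyrus,left,occipital,TRUE
L_lateral_occipital_gyrus_superior,left,occipital,TRUE
L_lateral_occipital_gyrus_inferior,left,occipital,TRUE
L_occipital_fusiform_gyrus,left,occipital,TRUE
L_occipitotemporal_junction,left,occipital,TRUE
R_precentral_gyrus,right,frontal,TRUE
R_superior_frontal_gyrus_medial,right,frontal,TRUE
R_superior_frontal_gyrus_lateral,right,frontal,TRUE
R_middle_frontal_gyrus_anterior,right,frontal,TRUE
R_middle_frontal_gyrus_posterior,right,frontal,TRUE
R_inferior_frontal_gyrus_opercularis,right,frontal,TRUE
R_inferior_frontal_gyrus_triangularis,right,frontal,TRUE
R_inferior_frontal_gyrus_orbitalis,right,frontal,TRUE
R_gyrus_rectus,right,frontal,TRUE
R_medial_orbital_gyrus,right,frontal,TRUE
R_lateral_orbital_gyrus,right,frontal,TRUE
R_anterior_orbital_gyrus,right,frontal,TRUE
R_posterior_orbital_gyrus,right,frontal,TRUE
R_frontal_operculum,right,frontal,TRUE
R_frontal_pole,right,frontal,TRUE
R_supplementary_motor_area,right,frontal,TRUE
R_anterior_cingulate_gyrus,right,frontal,TRUE
R_middle_cingulate_gyrus,right,frontal,TRUE
R_paracentral_lobule_anterior,right,frontal,TRUE
R_precentral_gyrus_medial,right,frontal,TRUE
R_olfactory_cortex,right,frontal,TRUE
R_frontomarginal_gyrus,right,frontal,TRUE
R_temporal_pole,right,temporal,TRUE
R_superior_temporal_gyrus_anterior,right,temporal,TRUE
R_superior_temporal_gyrus_posterior,right,temporal,TRUE
R_middle_temporal_gyrus_anterior,right,temporal,TRUE
R_middle_temporal_gyrus_posterior,right,temporal,TRUE
R_inferior_temporal_gyrus,right,temporal,TRUE
R_fusiform_gyrus_anterior,right,temporal,TRUE
R_fusiform_gyrus_posterior,right,temporal,TRUE
R_parahippocampal_gyrus,right,temporal,TRUE
R_planum_polare,right,temporal,TRUE
R_planum_temporale,right,temporal,TRUE
R_heschls_gyrus,right,temporal,TRUE
R_postcentral_gyrus,right,parietal,TRUE
R_superior_parietal_lobule,right,parietal,TRUE
R_supramarginal_gyrus,right,parietal,TRUE
R_angular_gyrus,right,parietal,TRUE
R_precuneus,right,parietal,TRUE
R_posterior_cingulate_gyrus,right,parietal,TRUE
R_paracentral_lobule_posterior,right,parietal,TRUE
R_parietal_operculum,right,parietal,TRUE
R_intraparietal_cortex,right,parietal,TRUE
R_occipital_pole,right,occipital,TRUE
R_calcarine_cortex,right,occipital,TRUE
R_cuneus,right,occipital,TRUE
R_lingual_gyrus,right,occipital,TRUE
R_lateral_occipital_gyrus_superior,right,occipital,TRUE
R_lateral_occipital_gyrus_inferior,right,occipital,TRUE
R_occipital_fusiform_gyrus,right,occipital,TRUE
R_occipitotemporal_junction,right,occipital,TRUE
L_hippocampus,left,subcortical_or_other,FALSE
L_amygdala,left,subcortical_or_other,FALSE
L_caudate_nucleus,left,subcortical_or_other,FALSE
L_putamen,left,subcortical_or_other,FALSE
L_pallidum,left,subcortical_or_other,FALSE
L_thalamus,left,subcortical_or_other,FALSE
L_nucleus_accumbens,left,subcortical_or_other,FALSE
L_insula,left,subcortical_or_other,FALSE
L_ventral_diencephalon,left,subcortical_or_other,FALSE
L_cerebellum_cortex,left,subcortical_or_other,FALSE
L_cerebellum_white_matter,left,subcortical_or_other,FALSE
L_basal_forebrain,left,subcortical_or_other,FALSE
L_substantia_nigra,left,subcortical_or_other,FALSE
L_subcallosal_area,left,subcortical_or_other,FALSE
R_hippocampus,right,subcortical_or_other,FALSE
R_amygdala,right,subcortical_or_other,FALSE
R_caudate_nucleus,right,subcortical_or_other,FALSE
R_putamen,right,subcortical_or_other,FALSE
R_pallidum,right,subcortical_or_other,FALSE
R_thalamus,right,subcortical_or_other,FALSE
R_nucleus_accumbens,right,subcortical_or_other,FALSE
R_insula,right,subcortical_or_other,FALSE
R_ventral_diencephalon,right,subcortical_or_other,FALSE
R_cerebellum_cortex,right,subcortical_or_other,FALSE
R_cerebellum_white_matter,right,subcortical_or_other,FALSE
R_basal_forebrain,right,subcortical_or_other,FALSE
R_substantia_nigra,right,subcortical_or_other,FALSE
R_subcallosal_area,right,subcortical_or_other,FALSE
brainstem,midline,subcortical_or_other,FALSE
corpus_callosum,midline,subcortical_or_other,FALSE
cerebellar_vermis,midline,subcortical_or_other,FALSE
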