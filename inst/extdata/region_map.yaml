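- voi_name: Frontal_DorsoMedial_L
  lobe: frontal
  hemisphere: left
- voi_name: Frontal_Orbital_L
  lobe: frontal
  hemisphere: left
- voi_name: Temporal_Sup_L
  lobe: lateral_temporal
  hemisphere: left
- voi_name: Temporal_Mid_L
  lobe: lateral_temporal
  hemisphere: left
- voi_name: Temporal_Inf_L
  lobe: lateral_temporal
  hemisphere: left
- voi_name: Parietal_Sup_L
  lobe: parietal
  hemisphere: left
- voi_name: Parietal_Inf_L
  lobe: parietal
  hemisphere: left
- voi_name: SupraMarginal_L
  lobe: parietal
  hemisphere: left
- voi_name: Angular_L
  lobe: parietal
  hemisphere: left
- voi_name: Precuneus_L
  lobe: parietal
  hemisphere: left
- voi_name: Cingulum_Ant_L
  lobe: cingulate
  hemisphere: left
- voi_name: Cingulum_Post_L
  lobe: cingulate
  hemisphere: left
- voi_name: Caudate_L
  lobe: striatum
  hemisphere: left
- voi_name: Putamen_L
  lobe: striatum
  hemisphere: left
- voi_name: Frontal_DorsoMedial_R
  lobe: frontal
  hemisphere: right
- voi_name: Frontal_Orbital_R
  lobe: frontal
  hemisphere: right
- voi_name: Temporal_Sup_R
  lobe: lateral_temporal
  hemisphere: right
- voi_name: Temporal_Mid_R
  lobe: lateral_temporal
  hemisphere: right
- voi_name: Temporal_Inf_R
  lobe: lateral_temporal
  hemisphere: right
- voi_name: Parietal_Sup_R
  lobe: parietal
  hemisphere: right
- voi_name: Parietal_Inf_R
  lobe: parietal
  hemisphere: right
- voi_name: SupraMarginal_R
  lobe: parietal
  hemisphere: right
- voi_name: Angular_R
  lobe: parietal
  hemisphere: right
- voi_name: Precuneus_R
  lobe: parietal
  hemisphere: right
- voi_name: Cingulum_Ant_R
  lobe: cingulate
  hemisphere: right
- voi_name: Cingulum_Post_R
  lobe: cingulate
  hemisphere: right
- voi_name: Caudate_R
  lobe: striatum
  hemisphere: right
- voi_name: Putamen_R
  lobe: striatum
  hemisphere: right
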