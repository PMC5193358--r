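dof_id,name,side,reference_max_torque_Nm,mirror_of,source,reference_knee_torque_Nm
ankle_r_sag,ankle right sagittal,right,76.7,ankle_l_sag,catalog-default,107.6
ankle_r_fro,ankle right frontal,right,30.4,ankle_l_fro,catalog-default,107.6
ankle_r_tra,ankle right transverse,right,20.3,ankle_l_tra,catalog-default,107.6
ankle_l_sag,ankle left sagittal,left,76.7,ankle_r_sag,catalog-default,107.6
ankle_l_fro,ankle left frontal,left,30.4,ankle_r_fro,catalog-default,107.6
ankle_l_tra,ankle left transverse,left,20.3,ankle_r_tra,catalog-default,107.6
knee_r_sag,knee right sagittal,right,107.6,knee_l_sag,catalog-default,107.6
knee_r_fro,knee right frontal,right,40.5,knee_l_fro,catalog-default,107.6
knee_r_tra,knee right transverse,right,20.3,knee_l_tra,catalog-default,107.6
knee_l_sag,knee left sagittal,left,107.6,knee_r_sag,catalog-default,107.6
knee_l_fro,knee left frontal,left,40.5,knee_r_fro,catalog-default,107.6
knee_l_tra,knee left transverse,left,20.3,knee_r_tra,catalog-default,107.6
hip_r_sag,hip right sagittal,right,121.6,hip_l_sag,catalog-default,107.6
hip_r_fro,hip right frontal,right,76,hip_l_fro,catalog-default,107.6
hip_r_tra,hip right transverse,right,45.6,hip_l_tra,catalog-default,107.6
hip_l_sag,hip left sagittal,left,121.6,hip_r_sag,catalog-default,107.6
hip_l_fro,hip left frontal,left,76,hip_r_fro,catalog-default,107.6
hip_l_tra,hip left transverse,left,45.6,hip_r_tra,catalog-default,107.6
wrist_r_sag,wrist right sagittal,right,6.1,wrist_l_sag,catalog-default,107.6
wrist_r_fro,wrist right frontal,right,4.6,wrist_l_fro,catalog-default,107.6
wrist_r_tra,wrist right transverse,right,3.5,wrist_l_tra,catalog-default,107.6
wrist_l_sag,wrist left sagittal,left,6.1,wrist_r_sag,catalog-default,107.6
wrist_l_fro,wrist left frontal,left,4.6,wrist_r_fro,catalog-default,107.6
wrist_l_tra,wrist left transverse,left,3.5,wrist_r_tra,catalog-default,107.6
elbow_r_sag,elbow right sagittal,right,36.5,elbow_l_sag,catalog-default,107.6
elbow_r_fro,elbow right frontal,right,12.2,elbow_l_fro,catalog-default,107.6
elbow_r_tra,elbow right transverse,right,6.1,elbow_l_tra,catalog-default,107.6
elbow_l_sag,elbow left sagittal,left,36.5,elbow_r_sag,catalog-default,107.6
elbow_l_fro,elbow left frontal,left,12.2,elbow_r_fro,catalog-default,107.6
elbow_l_tra,elbow left transverse,left,6.1,elbow_r_tra,catalog-default,107.6
shoulder_r_sag,shoulder right sagittal,right,46.6,shoulder_l_sag,catalog-default,107.6
shoulder_r_fro,shoulder right frontal,right,34.4,shoulder_l_fro,catalog-default,107.6
shoulder_r_tra,shoulder right transverse,right,24.3,shoulder_l_tra,catalog-default,107.6
shoulder_l_sag,shoulder left sagittal,left,46.6,shoulder_r_sag,catalog-default,107.6
shoulder_l_fro,shoulder left frontal,left,34.4,shoulder_r_fro,catalog-default,107.6
shoulder_l_tra,shoulder left transverse,left,24.3,shoulder_r_tra,catalog-default,107.6
neck_c_sag,neck central sagittal,central,21.3,,catalog-default,107.6
neck_c_fro,neck central frontal,central,18.2,,catalog-default,107.6
neck_c_tra,neck central transverse,central,11.1,,catalog-default,107.6
waist_c_sag,waist central sagittal,central,91.2,,catalog-default,107.6
waist_c_fro,waist central frontal,central,73.5,,catalog-default,107.6
waist_c_tra,waist central transverse,central,44.6,,catalog-default,107.6
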