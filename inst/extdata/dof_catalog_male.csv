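dof_id,name,side,reference_max_torque_Nm,mirror_of,source,reference_knee_torque_Nm
ankle_r_sag,ankle right sagittal,right,151.5,ankle_l_sag,published-male-sagittal,212.4
ankle_r_fro,ankle right frontal,right,60,ankle_l_fro,catalog-default,212.4
ankle_r_tra,ankle right transverse,right,40,ankle_l_tra,catalog-default,212.4
ankle_l_sag,ankle left sagittal,left,151.5,ankle_r_sag,published-male-sagittal,212.4
ankle_l_fro,ankle left frontal,left,60,ankle_r_fro,catalog-default,212.4
ankle_l_tra,ankle left transverse,left,40,ankle_r_tra,catalog-default,212.4
knee_r_sag,knee right sagittal,right,212.4,knee_l_sag,catalog-default,212.4
knee_r_fro,knee right frontal,right,80,knee_l_fro,catalog-default,212.4
knee_r_tra,knee right transverse,right,40,knee_l_tra,catalog-default,212.4
knee_l_sag,knee left sagittal,left,212.4,knee_r_sag,catalog-default,212.4
knee_l_fro,knee left frontal,left,80,knee_r_fro,catalog-default,212.4
knee_l_tra,knee left transverse,left,40,knee_r_tra,catalog-default,212.4
hip_r_sag,hip right sagittal,right,240.1,hip_l_sag,published-male-sagittal,212.4
hip_r_fro,hip right frontal,right,150,hip_l_fro,catalog-default,212.4
hip_r_tra,hip right transverse,right,90,hip_l_tra,catalog-default,212.4
hip_l_sag,hip left sagittal,left,240.1,hip_r_sag,published-male-sagittal,212.4
hip_l_fro,hip left frontal,left,150,hip_r_fro,catalog-default,212.4
hip_l_tra,hip left transverse,left,90,hip_r_tra,catalog-default,212.4
wrist_r_sag,wrist right sagittal,right,12,wrist_l_sag,catalog-default,212.4
wrist_r_fro,wrist right frontal,right,9,wrist_l_fro,catalog-default,212.4
wrist_r_tra,wrist right transverse,right,7,wrist_l_tra,catalog-default,212.4
wrist_l_sag,wrist left sagittal,left,12,wrist_r_sag,catalog-default,212.4
wrist_l_fro,wrist left frontal,left,9,wrist_r_fro,catalog-default,212.4
wrist_l_tra,wrist left transverse,left,7,wrist_r_tra,catalog-default,212.4
elbow_r_sag,elbow right sagittal,right,72,elbow_l_sag,catalog-default,212.4
elbow_r_fro,elbow right frontal,right,24,elbow_l_fro,catalog-default,212.4
elbow_r_tra,elbow right transverse,right,12,elbow_l_tra,catalog-default,212.4
elbow_l_sag,elbow left sagittal,left,72,elbow_r_sag,catalog-default,212.4
elbow_l_fro,elbow left frontal,left,24,elbow_r_fro,catalog-default,212.4
elbow_l_tra,elbow left transverse,left,12,elbow_r_tra,catalog-default,212.4
shoulder_r_sag,shoulder right sagittal,right,92,shoulder_l_sag,catalog-default,212.4
shoulder_r_fro,shoulder right frontal,right,68,shoulder_l_fro,catalog-default,212.4
shoulder_r_tra,shoulder right transverse,right,48,shoulder_l_tra,catalog-default,212.4
shoulder_l_sag,shoulder left sagittal,left,92,shoulder_r_sag,catalog-default,212.4
shoulder_l_fro,shoulder left frontal,left,68,shoulder_r_fro,catalog-default,212.4
shoulder_l_tra,shoulder left transverse,left,48,shoulder_r_tra,catalog-default,212.4
neck_c_sag,neck central sagittal,central,42,,catalog-default,212.4
neck_c_fro,neck central frontal,central,36,,catalog-default,212.4
neck_c_tra,neck central transverse,central,22,,catalog-default,212.4
waist_c_sag,waist central sagittal,central,180,,catalog-default,212.4
waist_c_fro,waist central frontal,central,145,,catalog-default,212.4
waist_c_tra,waist central transverse,central,88,,catalog-default,212.4
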