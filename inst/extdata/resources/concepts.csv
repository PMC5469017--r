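# Standardized measurement concept inventory (27 concepts).
# concept_id,label,value_kind,units,anatomy_tags,measure_tags
# Multi-valued fields are ';'-separated.
aortic_valve_max_pressure_gradient,Aortic valve max pressure gradient,QUANTITATIVE,mmhg,aortic,pressure;gradient
aortic_valve_mean_pressure_gradient,Aortic valve mean pressure gradient,QUANTITATIVE,mmhg,aortic,pressure;gradient
aortic_valve_orifice_area,Aortic valve orifice area,QUANTITATIVE,cm2,aortic,area
aortic_valve_regurgitation,Aortic valve regurgitation,QUALITATIVE,,aortic,regurgitation
aortic_valve_regurgitation_peak_velocity,Aortic valve regurgitation peak velocity,QUANTITATIVE,m_s;cm_s,aortic,regurgitation;velocity
aortic_valve_stenosis,Aortic valve stenosis,QUALITATIVE,,aortic,stenosis
e_e_prime_ratio,E/e prime ratio,QUANTITATIVE,,,ratio
interventricular_septum_dimension_end_diastole,Interventricular septum dimension at end diastole,QUANTITATIVE,mm;cm,septum,dimension
left_atrium_size_end_systole,Left atrium size at end systole,BOTH,mm;cm,atrium,size;dimension
left_ventricular_contractility,Left ventricular contractility,QUALITATIVE,,ventricle,contractility
left_ventricular_dimension_end_diastole,Left ventricular dimension at end diastole,QUANTITATIVE,mm;cm,ventricle,dimension
left_ventricular_dimension_end_systole,Left ventricular dimension at end systole,QUANTITATIVE,mm;cm,ventricle,dimension
left_ventricular_ejection_fraction,Left ventricular ejection fraction,BOTH,percent,ventricle,fraction
left_ventricular_hypertrophy,Left ventricular hypertrophy,QUALITATIVE,,ventricle,hypertrophy
left_ventricular_posterior_wall_thickness_end_diastole,Left ventricular posterior wall thickness at end diastole,QUANTITATIVE,mm;cm,ventricle;posterior_wall,dimension
left_ventricular_size,Left ventricular size,QUALITATIVE,,ventricle,size
mitral_valve_mean_pressure_gradient,Mitral valve mean pressure gradient,QUANTITATIVE,mmhg,mitral,pressure;gradient
mitral_valve_orifice_area,Mitral valve orifice area,QUANTITATIVE,cm2,mitral,area
mitral_valve_regurgitation,Mitral valve regurgitation,QUALITATIVE,,mitral,regurgitation
mitral_valve_regurgitation_peak_velocity,Mitral valve regurgitation peak velocity,QUANTITATIVE,m_s;cm_s,mitral,regurgitation;velocity
mitral_valve_stenosis,Mitral valve stenosis,QUALITATIVE,,mitral,stenosis
pulmonary_artery_pressure,Pulmonary artery pressure,QUANTITATIVE,mmhg,pulmonary,pressure
right_atrial_pressure,Right atrial pressure,QUANTITATIVE,mmhg,atrium,pressure
tricuspid_valve_mean_pressure_gradient,Tricuspid valve mean pressure gradient,QUANTITATIVE,mmhg,tricuspid,pressure;gradient
tricuspid_valve_orifice_area,Tricuspid valve orifice area,QUANTITATIVE,cm2,tricuspid,area
tricuspid_valve_regurgitation,Tricuspid valve regurgitation,QUALITATIVE,,tricuspid,regurgitation
tricuspid_valve_regurgitation_peak_velocity,Tricuspid valve regurgitation peak velocity,QUANTITATIVE,m_s;cm_s,tricuspid,regurgitation;velocity
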