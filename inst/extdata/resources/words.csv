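# Anatomy/measure word lexicon: surface,category,group
# category is ANATOMY or MEASURE; group_id is the canonical semantic group
# shared by variants and misspellings of the same word.
left,ANATOMY,laterality
right,ANATOMY,laterality
ventricle,ANATOMY,ventricle
ventricular,ANATOMY,ventricle
ventricles,ANATOMY,ventricle
atrium,ANATOMY,atrium
atrial,ANATOMY,atrium
atria,ANATOMY,atrium
mitral,ANATOMY,mitral
tricuspid,ANATOMY,tricuspid
aortic,ANATOMY,aortic
aorta,ANATOMY,aortic
pulmonary,ANATOMY,pulmonary
pulmonic,ANATOMY,pulmonary
septum,ANATOMY,septum
septal,ANATOMY,septum
interventricular,ANATOMY,septum
posterior,ANATOMY,posterior_wall
wall,ANATOMY,posterior_wall
valve,ANATOMY,valve
valvular,ANATOMY,valve
artery,ANATOMY,vessel
dimension,MEASURE,dimension
dimensions,MEASURE,dimension
diameter,MEASURE,dimension
thickness,MEASURE,dimension
size,MEASURE,size
area,MEASURE,area
volume,MEASURE,volume
velocity,MEASURE,velocity
velocities,MEASURE,velocity
pressure,MEASURE,pressure
pressures,MEASURE,pressure
gradient,MEASURE,gradient
fraction,MEASURE,fraction
ejection,MEASURE,fraction
ratio,MEASURE,ratio
regurgitation,MEASURE,regurgitation
regurgitant,MEASURE,regurgitation
insufficiency,MEASURE,regurgitation
stenosis,MEASURE,stenosis
stenotic,MEASURE,stenosis
hypertrophy,MEASURE,hypertrophy
contractility,MEASURE,contractility
function,MEASURE,contractility
end,MEASURE,phase
diastolic,MEASURE,phase
diastole,MEASURE,phase
systolic,MEASURE,phase
systole,MEASURE,phase
peak,MEASURE,aggregate
max,MEASURE,aggregate
maximum,MEASURE,aggregate
mean,MEASURE,aggregate
jet,MEASURE,aggregate
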