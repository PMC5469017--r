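# Unit table: unit_id,surfaces,dimension  (surfaces ';'-separated)
percent,%;percent;per cent,percent
mm,mm;millimeter;millimeters,length_mm
cm,cm;centimeter;centimeters,length_cm
cm2,cm2;cm^2;sq cm;square centimeters,area_cm2
m_s,m/s;m/sec;meters per second,velocity_m_s
cm_s,cm/s;cm/sec,velocity_cm_s
mmhg,mmhg;mm hg,pressure_mmHg
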