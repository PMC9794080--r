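name,value,comment
hr_max,100,"tachycardia cutoff, bpm (clinical convention)"
rmssd_max,0.05,"irregular-rhythm cutoff on RMSSD, s"
st_normal,-0.035,"normal ST level mean, mV (reference table, normal column)"
st_dev_max,0.1,"max |ST - normal| before flagging, mV (~3x reported std, rounded)"
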