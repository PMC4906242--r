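column,type,units,description
bouton_id,string,,unique bouton identifier (field-scoped)
prep_id,string,,neuron preparation (culture) identifier
field_id,string,,imaged field identifier
group,string,,experimental condition label
qc_status,string,,kept | excluded:baseline_drift | excluded:nh4cl_invalid
exo_rate,numeric,normalized dF per second,6-point OLS slope of the Baf-train rise
exo_r2,numeric,,R-squared of the exocytic fit
endo_rate,numeric,normalized dF per second,6-point OLS slope of the (Baf - first) difference trace taken 9 frames after onset
endo_r2,numeric,,R-squared of the endocytic fit
exo_amplitude,numeric,fraction of NH4Cl signal,peak of the Baf-train response
net_amplitude,numeric,fraction of NH4Cl signal,peak of the first-train response
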