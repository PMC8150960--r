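file,column,type,units,description
raw_signal.csv,timestamp_iso,character,ISO 8601,sample timestamp with fractional seconds
raw_signal.csv,x_g,numeric,g,acceleration along axis 1
raw_signal.csv,y_g,numeric,g,acceleration along axis 2
raw_signal.csv,z_g,numeric,g,acceleration along axis 3
breaths.csv,timestamp_iso,character,ISO 8601,breath timestamp
breaths.csv,vo2_mlmin,numeric,mL/min,oxygen uptake of the breath
breaths.csv,vco2_mlmin,numeric,mL/min,carbon dioxide output of the breath
annotation.csv,participant,character,,participant identifier
annotation.csv,activity,character,,activity label
annotation.csv,start_iso,character,ISO 8601,bout start
annotation.csv,end_iso,character,ISO 8601,bout end
epochs.csv,participant,character,,participant identifier
epochs.csv,site,character,,wear site (hip / nondom_wrist / dom_wrist)
epochs.csv,activity,character,,activity label
epochs.csv,epoch_start_s,numeric,s,epoch start relative to recording start
epochs.csv,enmo_mg,numeric,mg,mean per-second ENMO over the epoch
epochs.csv,counts_per_epoch,integer,counts,vector-magnitude activity counts summed over the epoch
epochs.csv,met,numeric,METs,steady-state MET of the parent activity
epochs.csv,intensity_class,character,,MET-derived class (ST / light / MVPA)
cutpoints.json,threshold,numeric,mg or counts,reported integer threshold
cutpoints.json,threshold_raw,numeric,mg or counts,raw midpoint threshold used for reuse
cutpoints.json,sensitivity,numeric,fraction,sensitivity at the selected threshold
cutpoints.json,specificity,numeric,fraction,specificity at the selected threshold
cutpoints.json,auc,numeric,fraction,area under the ROC curve
cutpoints.json,auc_lo,numeric,fraction,DeLong 95% interval lower bound
cutpoints.json,auc_hi,numeric,fraction,DeLong 95% interval upper bound
cutpoints.json,grade,character,,accuracy grade (poor / fair / good / excellent)
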