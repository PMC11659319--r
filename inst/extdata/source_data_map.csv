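canonical,source
id,Participant
age,Age
sex,Sex
pta,PTA
wave_i_latency,Wave I Latency
wave_i_amplitude,Wave I Amplitude
wave_v_latency,Wave V Latency
wave_v_amplitude,Wave V Amplitude
word_learning,Word Learning
delayed_recall,Delayed Recall
word_recognition,Word Recognition
animal_fluency,Animal Fluency
tmt_a,TMT A
tmt_b,TMT B
fmt_accuracy,4MT Accuracy
fmt_rt,4MT RT
visual_discrimination,Visual Discrimination
sdmt,SDMT
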