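# Adapter template: maps an externally deposited recording folder onto the
# nwreflex bundle schema. Deposited folders from other acquisition pipelines
# do not document a fixed internal layout, so EDIT this file to match the
# actual files before use; the values below describe the expected shape only.
#
# channels: one entry per file holding a rate group of channels.
#   file:        CSV inside the recording folder
#   rate_hz:     sampling rate of every column in that file
#   time_column: name of the time column (seconds); optional, default time_s
#   map:         original column name -> canonical channel name
#                (EMG: APB BRD BBL TRI AD PD ESR ESL; force: Fx Fy Fz Mx My Mz)
channels:
  - file: emg.csv
    rate_hz: 2000
    time_column: time_s
    map:
      apb: APB
      brd: BRD
      bbl: BBL
      tri: TRI
      ad: AD
      pd: PD
      esr: ESR
      esl: ESL
  - file: force.csv
    rate_hz: 200
    time_column: time_s
    map:
      fx: Fx
      fy: Fy
      fz: Fz
      mx: Mx
      my: My
      mz: Mz

# events: stimulus train onsets. Train parameters default to the standard
# reflex-eliciting train (10 pulses, 200 us, 300 Hz) when not given.
events:
  file: stim.csv
  onset_column: onset_s
  n_pulses: 10
  pulse_width_us: 200
  pulse_rate_hz: 300

# layout: task is joint_position or conditioning; condition one of
# ELB_FLEX ELB_EXT NEUT SHL_FLEX SHL_EXT NEUT_REPEAT (joint_position) or
# EXT_PRE EXT_POST FLEX_PRE FLEX_POST (conditioning).
layout:
  task: conditioning
  condition: EXT_PRE
  subject_id: S01
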