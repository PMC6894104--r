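prn
insulin
aspirin
metformin
lisinopril
tablet
daily
patient
history
exam
blood
pressure
stable
follow
clinic
discharge
review
normal
chest
report
noted
plan
continue
status
seen
visit
pain
left
right
with
without
home
care
dose
oral
twice
once
weekly
return
weeks
months
symptoms
denies
reports
impression
findings
contrast
unremarkable
medication
refill
given
started
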