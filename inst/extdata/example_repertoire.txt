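# Synthetic wild-type repertoire for the bundled example records.
# One behavior category per line; comments and blank lines are ignored.
rest
forage
groom
play
travel
vigilance
social
nest_build
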