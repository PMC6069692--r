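# Type-preserving phrase templates. One template per line, with exactly one
# bracketed placeholder naming the mention class the phrase preserves.
# Placeholder classes: Event-Problem, Event-Treatment, Event-Test,
# Time-Date, Time-Duration, Time-Time, Time-Frequency.
the first course of [Event-Treatment]
episodes of [Event-Problem]
an episode of [Event-Problem]
the time of [Time-Date]
period of [Time-Duration]
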