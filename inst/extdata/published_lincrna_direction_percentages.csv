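direction_category,percent
up_up,12.9
down_down,55.6
up_down,8.0
down_up,22.5
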