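aliquot_volume_ul: 1.5
tip_volume_ul: 10
part_order: as_read
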