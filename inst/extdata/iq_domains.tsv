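protein	domain_string	reported_variant	reported_count
NLRP3	322WQKAERGDILLSSL335	IQ-like	1
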