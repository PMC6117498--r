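^[0-9]{2}(\.[0-9])?°C$	#BODY_TEMPERATURE#
^[0-9]{1,3}yo$	#AGE#
^[0-9]{2,3}cm$	#HEIGHT#
^[0-9]{2,3}kg$	#WEIGHT#
^[0-9]{4}-[0-9]{2}-[0-9]{2}$	#DATE#
^[0-9]{1,2}:[0-9]{2}$	#TIME#
^[¥$][0-9]+(\.[0-9]{2})?$	#MONEY#
^[0-9]+(\.[0-9]+)?%$	#PERCENT#
^[0-9]+$	#NUMBER#
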