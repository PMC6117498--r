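w0001.a	w0001
w0001.b	w0001
w0002.a	w0002
w0002.b	w0002
w0003.a	w0003
w0003.b	w0003
w0004.a	w0004
w0004.b	w0004
w0005.a	w0005
w0005.b	w0005
w0006.a	w0006
w0006.b	w0006
w0007.a	w0007
w0007.b	w0007
w0008.a	w0008
w0008.b	w0008
w0009.a	w0009
w0009.b	w0009
w0010.a	w0010
w0010.b	w0010
w0011.a	w0011
w0011.b	w0011
w0012.a	w0012
w0012.b	w0012
w0013.a	w0013
w0013.b	w0013
w0014.a	w0014
w0014.b	w0014
w0015.a	w0015
w0015.b	w0015
w0016.a	w0016
w0016.b	w0016
w0017.a	w0017
w0017.b	w0017
w0018.a	w0018
w0018.b	w0018
w0019.a	w0019
w0019.b	w0019
w0020.a	w0020
w0020.b	w0020
w0021.a	w0021
w0021.b	w0021
w0022.a	w0022
w0022.b	w0022
w0023.a	w0023
w0023.b	w0023
w0024.a	w0024
w0024.b	w0024
w0025.a	w0025
w0025.b	w0025
w0026.a	w0026
w0026.b	w0026
w0027.a	w0027
w0027.b	w0027
w0028.a	w0028
w0028.b	w0028
w0029.a	w0029
w0029.b	w0029
w0030.a	w0030
w0030.b	w0030
w0031.a	w0031
w0031.b	w0031
w0032.a	w0032
w0032.b	w0032
w0033.a	w0033
w0033.b	w0033
w0034.a	w0034
w0034.b	w0034
w0035.a	w0035
w0035.b	w0035
w0036.a	w0036
w0036.b	w0036
w0037.a	w0037
w0037.b	w0037
w0038.a	w0038
w0038.b	w0038
w0039.a	w0039
w0039.b	w0039
w0040.a	w0040
w0040.b	w0040
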