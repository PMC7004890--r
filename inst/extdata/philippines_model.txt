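# retkin 0.1.0
# units: rates 1/day, delays day
[rates]
L(4,3) = 0.8
L(0,3) = 0.2
L(5,4) = 1.22
L(6,5) = 12.3
L(7,5) = 3.07
L(5,6) = 0.00884
L(5,7) = 0.34
L(10,6) = 0.00194
L(8,5) = 2.21
L(10,8) = 1
[delays]
DT(3) = 0.206
DT(8) = 0.0520833333333
[status]
DT(3) = adjustable
L(5,4) = adjustable
L(6,5) = adjustable
L(7,5) = adjustable
L(5,6) = adjustable
L(5,7) = adjustable
L(10,6) = adjustable
L(4,3) = fixed
L(0,3) = fixed
L(8,5) = fixed
L(10,8) = fixed
DT(8) = fixed
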