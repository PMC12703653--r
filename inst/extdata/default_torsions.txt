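PATTERN [C:1][C:2][O:3][C:4]
BANDWIDTH 10
PEAK 180 0.51000494217856229
PEAK  75 0.25500014068555321
PEAK -77 0.23499491713588458

PATTERN [C:1][C:2][C:3][C:4]
BANDWIDTH 10
PEAK 179 0.63250011706291709
PEAK  64 0.21249994004289194
PEAK -65 0.15499994289419103

PATTERN [C:1][C:2][N:3][C:4]
BANDWIDTH 10
PEAK 179 0.66501454887416311
PEAK  80 0.17999732132825061
PEAK -79 0.15498812979758636

PATTERN [c:1][c:2][C:3][C:4]
BANDWIDTH 10
PEAK  90 0.36505560468613196
PEAK -90 0.32510388226736614
PEAK 178 0.15738150806279200
PEAK  -1 0.15245900498370993

PATTERN *
BANDWIDTH 10
PEAK 180 0.50
PEAK  60 0.25
PEAK -60 0.25

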