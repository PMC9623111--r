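### synthetic SVC-style leaf record (generated, not an instrument export)
### columns: wavelength_nm reference_radiance target_radiance percent
350.0 78.19 8.95 11.45
400.0 79.72 9.70 12.17
450.0 82.68 9.65 11.67
500.0 85.32 10.73 12.58
550.0 87.70 10.37 11.82
600.0 89.95 11.05 12.28
650.0 93.26 11.79 12.64
700.0 94.95 21.31 22.44
750.0 98.51 48.36 49.09
800.0 99.97 52.10 52.12
850.0 103.15 53.67 52.03
900.0 106.14 55.31 52.11
950.0 106.81 55.83 52.27
1000.0 109.86 57.17 52.04
1050.0 112.43 57.12 50.80
1100.0 115.32 60.10 52.12
1150.0 117.36 60.85 51.85
1200.0 118.67 61.80 52.08
1250.0 121.28 63.35 52.23
1300.0 125.66 66.05 52.56
1350.0 127.35 65.85 51.71
1400.0 129.11 67.81 52.52
1450.0 132.41 69.03 52.13
1500.0 135.61 71.08 52.42
1550.0 138.45 72.50 52.37
1600.0 139.78 73.09 52.29
1650.0 142.37 73.44 51.58
1700.0 144.12 74.89 51.96
1750.0 147.73 77.19 52.25
1800.0 149.68 77.26 51.62
1850.0 152.73 79.09 51.78
1900.0 155.35 81.14 52.23
1950.0 158.02 82.66 52.31
2000.0 159.70 83.34 52.19
2050.0 162.75 84.05 51.64
2100.0 164.14 84.63 51.56
2150.0 167.11 87.91 52.61
2200.0 169.57 88.35 52.10
2250.0 171.29 89.13 52.03
2300.0 175.02 90.93 51.95
2350.0 177.60 91.50 51.52
2400.0 179.82 93.95 52.25
2450.0 182.88 94.94 51.91
2500.0 184.64 95.88 51.93
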