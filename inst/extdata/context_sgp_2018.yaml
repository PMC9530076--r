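# Economic context: NHS Scotland perspective, 2018 prices.
# inflation_index holds ONS RPI annual averages (1987 = 100); extend or
# replace the series to use another price window or index.
base_year: 2018
discount_rate: 0.035
vat_rate: 0.20
samples_per_trio: 3
inflation_index:
  "2013": 250.1
  "2014": 255.7
  "2015": 257.0
  "2016": 263.1
  "2017": 272.5
  "2018": 278.1
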