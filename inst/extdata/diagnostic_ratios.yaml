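# Nine PAH diagnostic ratios with threshold -> source-label intervals.
# Bounds: missing lower/upper = open-ended; `strict: true` on a side means
# the bound itself is excluded (printed "<a" / ">b"); printed ranges a-b
# are closed on both sides, so ties at a shared boundary land in the range
# interval. Values falling in no interval classify as "indeterminate".
rules:
  - name: "Anthracene/(Anthracene + Phenanthrene)"
    numerator: [anthracene]
    denominator: [anthracene, phenanthrene]
    intervals:
      - {upper: 0.1, upper_strict: true, label: "Petroleum"}
      - {lower: 0.1, lower_strict: true, label: "Combustion"}
  - name: "Fluoranthene/(Fluoranthene + Pyrene)"
    numerator: [fluoranthene]
    denominator: [fluoranthene, pyrene]
    intervals:
      - {upper: 0.4, upper_strict: true, label: "Petroleum"}
      - {lower: 0.4, upper: 0.5, label: "Liquid fossil fuel combustion"}
      - {lower: 0.5, lower_strict: true, label: "Coal, wood or grass combustion"}
  - name: "Benz[a]anthracene/(Benz[a]anthracene + Chrysene)"
    numerator: ["benz[a]anthracene"]
    denominator: ["benz[a]anthracene", chrysene]
    intervals:
      - {upper: 0.2, upper_strict: true, label: "Petroleum"}
      - {lower: 0.2, upper: 0.35, label: "Petroleum or combustion"}
      - {lower: 0.35, lower_strict: true, label: "Combustion"}
  - name: "Phenanthrene/Anthracene"
    numerator: [phenanthrene]
    denominator: [anthracene]
    amended: true
    note: >-
      Printed thresholds ("<10 pyrogenic", "<15 petrogenic") overlap and
      contradict each other below 10; amended to <10 pyrogenic, >15
      petrogenic, 10-15 indeterminate.
    intervals:
      - {upper: 10, upper_strict: true, label: "Pyrogenic"}
      - {lower: 15, lower_strict: true, label: "Petrogenic"}
  - name: "Indeno[1,2,3-cd]pyrene/Benzo[ghi]perylene"
    numerator: ["indeno[1,2,3-cd]pyrene"]
    denominator: ["benzo[ghi]perylene"]
    intervals:
      - {upper: 0.2, upper_strict: true, label: "Petrogenic"}
      - {lower: 0.2, upper: 0.5, label: "Fuel combustion (vehicle and crude oil)"}
      - {lower: 0.5, lower_strict: true, label: "Coal, wood or grass combustion"}
  - name: "Benzo[a]pyrene/(Benzo[a]pyrene + Chrysene)"
    numerator: ["benzo[a]pyrene"]
    denominator: ["benzo[a]pyrene", chrysene]
    intervals:
      - {upper: 0.2, upper_strict: true, label: "Petroleum"}
      - {lower: 0.2, upper: 0.35, label: "Coal, wood or grass combustion"}
      - {lower: 0.35, lower_strict: true, label: "Fuel combustion (vehicle)"}
  - name: "Fluoranthene/Pyrene"
    numerator: [fluoranthene]
    denominator: [pyrene]
    intervals:
      - {upper: 1, upper_strict: true, label: "Petrogenic"}
      - {lower: 1, lower_strict: true, label: "Pyrogenic"}
  - name: "Benzo[a]pyrene/Benzo[ghi]perylene"
    numerator: ["benzo[a]pyrene"]
    denominator: ["benzo[ghi]perylene"]
    intervals:
      - {lower: 0.6, lower_strict: true, label: "Fuel combustion (vehicle)"}
  - name: "HMW/LMW PAHs"
    numerator: [HMW]
    denominator: [LMW]
    intervals:
      - {upper: 1, upper_strict: true, label: "Petrogenic"}
      - {lower: 1, lower_strict: true, label: "Pyrogenic"}
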