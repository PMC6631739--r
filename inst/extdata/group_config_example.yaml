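# Example group-config for read_panel(group_config=...): reassigns a
# country's MDG region and/or income tier, overriding the panel columns.
# Region labels: DR, SA, CCA, EA, LAC, NAME, SEA, SSA.
# Income labels: high+upper-middle, lower-middle+low.
countries:
  SYN001:
    region: SSA
    income_group: lower-middle+low
  SYN002:
    region: DR
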