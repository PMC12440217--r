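# Built-in gene-family definitions for the envC--sddA neighborhood analysis.
# Each family is a boolean query over namespaced annotation terms:
#   include: gene matches if it carries at least one of these
#   exclude: gene is rejected if it carries any of these
#   require: gene must carry all of these
# Copy this file and pass it to builtin_query(config=...) to redefine
# families when PFAM/KEGG/TIGRFAM assignments drift between database
# releases.
sddA:
  include: [PFAM:PF04748, KEGG:K09798]
envC:
  include: [KEGG:K22719]
  exclude: [KEGG:K19304, KEGG:K06194, KEGG:K12943]
gpmM:
  include: [TIGRFAM:TIGR01307]
amiC:
  include: [KEGG:K01448, PFAM:PF01520]
  require: [PFAM:PF11741]
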