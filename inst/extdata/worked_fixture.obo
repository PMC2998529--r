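format-version: 1.2
! synthetic worked fixture: 14 cellular_component-style terms,
! two informative sub-graphs under GO:0000005 and GO:0000006 at
! topology cutoff 1.2, remaining terms at the meta level.

[Term]
id: GO:0000001
name: cell compartment root
namespace: cellular_component

[Term]
id: GO:0000002
name: membrane side
namespace: cellular_component
is_a: GO:0000001 ! cell compartment root

[Term]
id: GO:0000003
name: intracellular part
namespace: cellular_component
is_a: GO:0000001 ! cell compartment root

[Term]
id: GO:0000004
name: cytoplasm-like region
namespace: cellular_component
is_a: GO:0000003 ! intracellular part

[Term]
id: GO:0000005
name: ribosome-like complex
namespace: cellular_component
alt_id: GO:0000105
is_a: GO:0000002 ! membrane side

[Term]
id: GO:0000006
name: vacuole-like organelle
namespace: cellular_component
is_a: GO:0000004 ! cytoplasm-like region

[Term]
id: GO:0000007
name: large subunit analogue
namespace: cellular_component
is_a: GO:0000005 ! ribosome-like complex

[Term]
id: GO:0000008
name: small subunit analogue
namespace: cellular_component
is_a: GO:0000005 ! ribosome-like complex

[Term]
id: GO:0000009
name: subunit interface
namespace: cellular_component
is_a: GO:0000007 ! large subunit analogue

[Term]
id: GO:0000010
name: subunit core
namespace: cellular_component
is_a: GO:0000007 ! large subunit analogue

[Term]
id: GO:0000011
name: vacuolar lumen analogue
namespace: cellular_component
is_a: GO:0000006 ! vacuole-like organelle

[Term]
id: GO:0000012
name: vacuolar membrane analogue
namespace: cellular_component
is_a: GO:0000006 ! vacuole-like organelle

[Term]
id: GO:0000013
name: lumen body
namespace: cellular_component
is_a: GO:0000011 ! vacuolar lumen analogue

[Term]
id: GO:0000014
name: membrane-lumen contact site
namespace: cellular_component
is_a: GO:0000012 ! vacuolar membrane analogue
relationship: part_of GO:0000011 ! vacuolar lumen analogue
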