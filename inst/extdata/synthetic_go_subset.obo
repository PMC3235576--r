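format-version: 1.2

[Term]
id: FX:0000001
name: biological_process
namespace: biological_process
is_a: 

[Term]
id: FX:0000002
name: biological regulation
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000040
name: metabolic process
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000100
name: immune system process
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000200
name: vesicle-mediated transport
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000300
name: cellular membrane organization
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000400
name: alcohol metabolic process
namespace: biological_process
is_a: FX:0000040

[Term]
id: FX:0000450
name: steroid metabolic process
namespace: biological_process
is_a: FX:0000040

[Term]
id: FX:0000470
name: cholesterol metabolic process
namespace: biological_process
is_a: FX:0000040

[Term]
id: FX:0000500
name: cell death/apoptosis
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000501
name: regulation of cell death
namespace: biological_process
is_a: FX:0000500
is_a: FX:0000002

[Term]
id: FX:0000600
name: lipid transport
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000602
name: low-density lipoprotein particle clearance
namespace: biological_process
is_a: FX:0000600

[Term]
id: FX:0000700
name: cell migration
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000900
name: background process 0
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000901
name: background process 1
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000902
name: background process 2
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000903
name: background process 3
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000904
name: background process 4
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000905
name: background process 5
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000906
name: background process 6
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000907
name: background process 7
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000908
name: background process 8
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000909
name: background process 9
namespace: biological_process
is_a: FX:0000001

[Term]
id: FX:0000999
name: deprecated assay artifact
namespace: biological_process
is_a: 
is_obsolete: true
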