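concept_id	name	source	is_preferred
cx:0001	Substantia nigra pars compacta	toy_atlas_a	true
cx:0001	substantia nigra compact part	toy_atlas_b	false
cx:0002	thalamic reticular nucleus	toy_atlas_a	true
cx:0003	dorsal raphe nucleus	toy_atlas_a	true
cx:0003	nucleus raphe dorsalis	toy_atlas_b	false
cx:0004	ventral tegmental area	toy_atlas_a	true
cx:0005	medial geniculate nucleus	toy_atlas_a	true
cx:0006	lateral geniculate nucleus	toy_atlas_a	true
cx:0007	caudate nucleus	toy_atlas_a	true
cx:0008	putamen	toy_atlas_a	true
cx:0009	globus pallidus	toy_atlas_a	true
cx:0010	subthalamic nucleus	toy_atlas_a	true
cx:0011	red nucleus	toy_atlas_a	true
cx:0012	inferior colliculus	toy_atlas_a	true
cx:0013	superior colliculus	toy_atlas_a	true
cx:0014	periaqueductal gray	toy_atlas_a	true
cx:0015	locus coeruleus	toy_atlas_a	true
cx:0016	nucleus accumbens	toy_atlas_a	true
cx:0017	olfactory bulb	toy_atlas_a	true
cx:0018	piriform cortex	toy_atlas_a	true
cx:0019	entorhinal cortex	toy_atlas_a	true
cx:0020	dentate gyrus	toy_atlas_a	true
cx:0021	hippocampus	toy_atlas_a	true
cx:0022	basolateral amygdala	toy_atlas_a	true
cx:0023	central amygdaloid nucleus	toy_atlas_a	true
cx:0024	bed nucleus of the stria terminalis	toy_atlas_a	true
cx:0025	medial septal nucleus	toy_atlas_a	true
cx:0026	diagonal band nucleus	toy_atlas_a	true
cx:0027	habenular nucleus	toy_atlas_b	true
cx:0027	habenula	toy_atlas_b	false
cx:0028	paraventricular hypothalamic nucleus	toy_atlas_a	true
cx:0029	supraoptic nucleus	toy_atlas_a	true
cx:0030	arcuate hypothalamic nucleus	toy_atlas_a	true
cx:0031	mammillary body	toy_atlas_a	true
cx:0032	anterior thalamic nucleus	toy_atlas_a	true
cx:0033	mediodorsal thalamic nucleus	toy_atlas_a	true
cx:0034	ventral posteromedial nucleus	toy_atlas_a	true
cx:0035	pontine nuclei	toy_atlas_a	true
cx:0036	cerebellar cortex	toy_atlas_a	true
cx:0037	fastigial nucleus	toy_atlas_a	true
cx:0038	dentate nucleus	toy_atlas_a	true
cx:0039	inferior olive	toy_atlas_a	true
cx:0040	nucleus of the solitary tract	toy_atlas_a	true
cx:0041	spinal trigeminal nucleus	toy_atlas_a	true
cx:0042	facial motor nucleus	toy_atlas_a	true
cx:0043	hypoglossal nucleus	toy_atlas_a	true
cx:0044	cochlear nuclear complex	toy_atlas_a	true
cx:0045	superior olivary complex	toy_atlas_a	true
cx:0046	primary somatosensory cortex	toy_atlas_a	true
cx:0047	primary motor cortex	toy_atlas_a	true
cx:0048	prefrontal cortex	toy_atlas_a	true
cx:0049	cingulate cortex	toy_atlas_a	true
cx:0050	zona incerta	toy_atlas_a	true
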