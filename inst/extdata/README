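Example input files in the package's text formats.

lattice3x3_edges.txt    edge list of a 3x3 periodic lattice: two 0-based
                        integer columns, one unordered edge per line,
                        '#' comments; '# n_nodes: K' declares the node
                        count.  Read with read_topology().
lattice3x3_configs.txt  20 two-state configurations on that lattice, one
                        per line, whitespace-delimited integers in
                        0..n_states-1.  Read with read_ensemble().
lattice3x3_params.json  the generating fields and couplings, with the
                        convention block ("pair_counting": "unordered",
                        "energy_scale": "extensive").  Read with
                        read_parameters().
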