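{"n_states":2,"h":[0,0.3],"J":{"spatial":[[-0.5,0.25],[0.25,-0.1]]},"convention":{"pair_counting":"unordered","energy_scale":"extensive"}}
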