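# BNF grammar generating partially connected three-layer SNN words.
# Dialect: "{" ends a hidden-neuron block, "(" ends an input-synapse
# config, "@" separates the neuron id, weight and delay of a config.
# The last config of each block is the synapse onto the output neuron.
# Alternative order is significant: codon c picks alternative c mod k.
<architecture> ::= <neuron> | <neuron> <architecture>
<neuron>       ::= <insyns> <outsyn> "{"
<insyns>       ::= <insyn> | <insyn> <insyns>
<insyn>        ::= <id> "@" <weight> "@" <delay> "("
<outsyn>       ::= "0" "@" <weight> "@" <delay>
<id>           ::= <digit> | <digit> <digit>
<weight>       ::= <wmag> | "-" <wmag>
<wmag>         ::= <wint> "." <digit> <digit>
<wint>         ::= <digit> | <digit> <digit> | <digit> <digit> <digit>
<delay>        ::= <dint> "." <digit> <digit>
<dint>         ::= <digit> | <digit> <digit>
<digit>        ::= "0" | "1" | "2" | "3" | "4" | "5" | "6" | "7" | "8" | "9"
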