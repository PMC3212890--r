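hello reference corpus (all files regenerable in code; see ?fixtures)

hello.owl.n3           ontology: NamedIndividual / GreetedIndividual (N3)
hello-description.n3   service interface document served by GET (N3)
hello-input.rdf.xml    invocation message: one NamedIndividual, foaf:name "Guy Incognito" (RDF/XML)
hello-output.rdf.xml   synchronous response: greeting "Hello, Guy Incognito!", root URI preserved (RDF/XML)
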