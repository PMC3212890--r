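@prefix mygrid: <http://www.mygrid.org.uk/mygrid-moby-service#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

_:input
    mygrid:objectType <http://sadiframework.org/examples/hello.owl#NamedIndividual> .

_:operation
    mygrid:inputParameter _:input ;
    mygrid:outputParameter _:output ;
    a mygrid:operation .

_:output
    mygrid:objectType <http://sadiframework.org/examples/hello.owl#GreetedIndividual> .

<http://sadiframework.org/examples/hello>
    <http://sadiframework.org/ontology/service.owl#asyncCapable> "false"^^xsd:boolean ;
    mygrid:authoritative "sadiframework.org" ;
    mygrid:hasOperation _:operation ;
    mygrid:hasServiceDescriptionText "Returns a greeting for each named individual." ;
    mygrid:hasServiceNameText "Hello" ;
    a mygrid:serviceDescription .

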