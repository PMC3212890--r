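#' Namespace and vocabulary constants
#'
#' Every well-known IRI used on the wire is fixed here, bit-exact, in one
#' place. The myGrid/Moby service-description terms in particular are the only
#' thing to adjust should wire-compatibility with historical service
#' descriptions require different predicate IRIs.
#'
#' @name vocab
#' @keywords internal
NULL

NS <- list(
  rdf    = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs   = "http://www.w3.org/2000/01/rdf-schema#",
  owl    = "http://www.w3.org/2002/07/owl#",
  xsd    = "http://www.w3.org/2001/XMLSchema#",
  foaf   = "http://xmlns.com/foaf/0.1/",
  mygrid = "http://www.mygrid.org.uk/mygrid-moby-service#"
)

RDF <- list(
  type      = paste0(NS$rdf, "type"),
  first     = paste0(NS$rdf, "first"),
  rest      = paste0(NS$rdf, "rest"),
  nil       = paste0(NS$rdf, "nil")
)

RDFS <- list(
  subClassOf  = paste0(NS$rdfs, "subClassOf"),
  isDefinedBy = paste0(NS$rdfs, "isDefinedBy"),
  comment     = paste0(NS$rdfs, "comment"),
  label       = paste0(NS$rdfs, "label")
)

OWL <- list(
  Class              = paste0(NS$owl, "Class"),
  Restriction        = paste0(NS$owl, "Restriction"),
  onProperty         = paste0(NS$owl, "onProperty"),
  someValuesFrom     = paste0(NS$owl, "someValuesFrom"),
  allValuesFrom      = paste0(NS$owl, "allValuesFrom"),
  minCardinality     = paste0(NS$owl, "minCardinality"),
  hasValue           = paste0(NS$owl, "hasValue"),
  intersectionOf     = paste0(NS$owl, "intersectionOf"),
  unionOf            = paste0(NS$owl, "unionOf"),
  complementOf       = paste0(NS$owl, "complementOf"),
  equivalentClass    = paste0(NS$owl, "equivalentClass"),
  DatatypeProperty   = paste0(NS$owl, "DatatypeProperty"),
  ObjectProperty     = paste0(NS$owl, "ObjectProperty"),
  Thing              = paste0(NS$owl, "Thing")
)

FOAF <- list(
  name = paste0(NS$foaf, "name")
)

# myGrid/Moby service ontology terms used by the description document.
MYGRID <- list(
  serviceDescription        = paste0(NS$mygrid, "serviceDescription"),
  operation                 = paste0(NS$mygrid, "operation"),
  parameter                 = paste0(NS$mygrid, "parameter"),
  hasOperation              = paste0(NS$mygrid, "hasOperation"),
  inputParameter            = paste0(NS$mygrid, "inputParameter"),
  outputParameter           = paste0(NS$mygrid, "outputParameter"),
  secondaryParameter        = paste0(NS$mygrid, "secondaryParameter"),
  objectType                = paste0(NS$mygrid, "objectType"),
  hasServiceNameText        = paste0(NS$mygrid, "hasServiceNameText"),
  hasServiceDescriptionText = paste0(NS$mygrid, "hasServiceDescriptionText"),
  authoritative             = paste0(NS$mygrid, "authoritative"),
  providedBy                = paste0(NS$mygrid, "providedBy")
)

# Terms minted by this stack (diagnostics and service annotations).
SADI <- list(
  ns           = "http://sadiframework.org/ontology/service.owl#",
  asyncCapable = "http://sadiframework.org/ontology/service.owl#asyncCapable",
  serviceError = "http://sadiframework.org/ontology/service.owl#serviceError"
)

XSD <- list(
  string             = paste0(NS$xsd, "string"),
  integer            = paste0(NS$xsd, "integer"),
  decimal            = paste0(NS$xsd, "decimal"),
  boolean            = paste0(NS$xsd, "boolean"),
  nonNegativeInteger = paste0(NS$xsd, "nonNegativeInteger")
)

# Media types accepted on the wire; anything else is a protocol error.
MEDIA_RDFXML <- "application/rdf+xml"
MEDIA_N3 <- "text/rdf+n3"
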