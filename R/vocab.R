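# Well-known RDF/OWL vocabulary IRIs used throughout the mapper.

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

rdf_iri  <- function(local) paste0(NS_RDF, local)
rdfs_iri <- function(local) paste0(NS_RDFS, local)
owl_iri  <- function(local) paste0(NS_OWL, local)
xsd_iri  <- function(local) paste0(NS_XSD, local)

RDF_TYPE   <- rdf_iri("type")
RDF_FIRST  <- rdf_iri("first")
RDF_REST   <- rdf_iri("rest")
RDF_NIL    <- rdf_iri("nil")

RDFS_SUBCLASSOF <- rdfs_iri("subClassOf")
RDFS_DOMAIN     <- rdfs_iri("domain")
RDFS_RANGE      <- rdfs_iri("range")

OWL_CLASS              <- owl_iri("Class")
OWL_ONTOLOGY           <- owl_iri("Ontology")
OWL_DATATYPE_PROPERTY  <- owl_iri("DatatypeProperty")
OWL_OBJECT_PROPERTY    <- owl_iri("ObjectProperty")
OWL_RESTRICTION        <- owl_iri("Restriction")
OWL_ON_PROPERTY        <- owl_iri("onProperty")
OWL_EQUIVALENT_CLASS   <- owl_iri("equivalentClass")
OWL_EQUIVALENT_PROP    <- owl_iri("equivalentProperty")
OWL_SYMMETRIC_PROPERTY <- owl_iri("SymmetricProperty")
OWL_TRANSITIVE_PROPERTY<- owl_iri("TransitiveProperty")
OWL_INVERSE_OF         <- owl_iri("inverseOf")
OWL_SAME_AS            <- owl_iri("sameAs")
OWL_DIFFERENT_FROM     <- owl_iri("differentFrom")
OWL_ALL_VALUES_FROM    <- owl_iri("allValuesFrom")
OWL_SOME_VALUES_FROM   <- owl_iri("someValuesFrom")
OWL_CARDINALITY        <- owl_iri("cardinality")
OWL_MIN_CARDINALITY    <- owl_iri("minCardinality")
OWL_MAX_CARDINALITY    <- owl_iri("maxCardinality")
OWL_ONE_OF             <- owl_iri("oneOf")
OWL_DATA_RANGE         <- owl_iri("DataRange")
OWL_UNION_OF           <- owl_iri("unionOf")

XSD_STRING   <- xsd_iri("string")
XSD_INTEGER  <- xsd_iri("integer")
XSD_INT      <- xsd_iri("int")
XSD_DOUBLE   <- xsd_iri("double")
XSD_BOOLEAN  <- xsd_iri("boolean")
XSD_DATE     <- xsd_iri("date")
XSD_DATETIME <- xsd_iri("dateTime")
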