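#' @name codonSelect-accessors
#' @title Accessor generics
#'
#' @description Small accessor generics shared across the package's classes:
#' taxon/leaf names, alignment dimensions, genetic-code access, foreground
#' flags and fitted quantities. Prefer these over direct slot access.
#'
#' @param x,object an object of the documented classes.
#' @param value replacement value.
#' @return the accessed component; see the individual class pages.
NULL

#' @rdname codonSelect-accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("siteCoordinates", function(x) standardGeneric("siteCoordinates"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("senseCodons", function(x) standardGeneric("senseCodons"))

#' Genetic code constructor / accessor generic
#'
#' For a numeric translation-table id this builds a [GeneticCode-class]
#' (see the method documentation); for a [CodonAlignment-class] it returns
#' the attached code.
#' @param x table id or object carrying a genetic code.
#' @export
setGeneric("geneticCode", function(x) standardGeneric("geneticCode"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("codonStates", function(x) standardGeneric("codonStates"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("foreground", function(x) standardGeneric("foreground"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("foreground<-", function(x, value) standardGeneric("foreground<-"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("branchLengths<-",
           function(x, value) standardGeneric("branchLengths<-"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("logLikelihood", function(x) standardGeneric("logLikelihood"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("mleParams", function(x) standardGeneric("mleParams"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' @rdname codonSelect-accessors
#' @export
setGeneric("posteriorTable", function(x) standardGeneric("posteriorTable"))
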