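#' Unit conversions for historical survey records
#'
#' Public Land Survey notes record diameters in inches and distances in
#' links or chains (1 chain = 66 ft = 100 links). The internal
#' representation is metric: diameters in cm, distances in m.
#'
#' @param x numeric vector.
#' @return Converted numeric vector.
#' @name pls_units
NULL

#' @rdname pls_units
#' @export
in_to_cm <- function(x) x * 2.54

#' @rdname pls_units
#' @export
cm_to_in <- function(x) x / 2.54

#' @rdname pls_units
#' @export
links_to_m <- function(x) x * 0.201168

#' @rdname pls_units
#' @export
chains_to_m <- function(x) x * 20.1168

#' @rdname pls_units
#' @export
m_to_links <- function(x) x / 0.201168
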