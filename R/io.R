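#' Serialize stage outputs to JSON
#'
#' Writes GC networks, synchrony catalogs, Tokeshi results and plain lists
#' to a documented JSON schema that [load_results()] reads back losslessly.
#'
#' @param results a \code{"gc_network"}, \code{"tokeshi_result"},
#'   \code{"synchrony_catalog"} or plain list/data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_results <- function(results, path) {
  kind <- class(results)[1]
  payload <- switch(kind,
    gc_network = list(kind = kind,
                      electrodes = results$electrodes,
                      alpha = results$alpha,
                      n_links = results$n_links,
                      links = results$links),
    tokeshi_result = c(list(kind = kind), unclass(results)),
    synchrony_catalog = list(kind = kind,
                             orders = results$orders,
                             groups = lapply(results$groups, function(g)
                               list(electrodes = g$electrodes,
                                    order = g$order,
                                    order_class = g$order_class))),
    list(kind = "list", value = results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back results written by [save_results()]
#'
#' @param path JSON file path.
#' @return the deserialized object; GC networks are restored with their
#'   class and link table.
#' @export
load_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$kind, "gc_network")) {
    links <- as.data.frame(x$links)
    if (!nrow(links))
      links <- data.frame(source = character(0), target = character(0),
                          D = numeric(0), p = numeric(0),
                          significant = logical(0))
    return(structure(list(links = links, n_links = x$n_links,
                          electrodes = x$electrodes, alpha = x$alpha),
                     class = "gc_network"))
  }
  if (identical(x$kind, "tokeshi_result")) {
    x$kind <- NULL
    return(structure(x, class = "tokeshi_result"))
  }
  if (identical(x$kind, "list")) return(x$value)
  x
}
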