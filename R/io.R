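#' Serialize fitted objects to JSON
#'
#' Writes a scaling model, PLS model or trained network to a plain JSON
#' file (all matrices stored dense, column names preserved), and reads it
#' back. Round-trips are exact to double precision as serialized by
#' `jsonlite` with `digits = NA`.
#'
#' @param x A `qsrr_scaling`, `qsrr_pls` or `qsrr_ann` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  cls <- intersect(class(x), c("qsrr_scaling", "qsrr_pls", "qsrr_ann"))
  if (!length(cls)) {
    stop("write_model_json(): unsupported object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  payload <- list(class = cls[1L], data = unclass(x))
  # named numeric vectors must become JSON objects, not bare arrays
  scaling_as_list <- function(s) {
    list(center = as.list(s$center), scale = as.list(s$scale), mode = s$mode)
  }
  if (cls[1L] == "qsrr_scaling") {
    payload$data <- scaling_as_list(payload$data)
  }
  if (cls[1L] == "qsrr_pls") {
    payload$data$x_scaling <- scaling_as_list(payload$data$x_scaling)
    payload$data$y_scaling <- scaling_as_list(payload$data$y_scaling)
  }
  if (cls[1L] == "qsrr_ann") {
    payload$data$x_scaling <- scaling_as_list(payload$data$x_scaling)
    payload$data$config <- unclass(payload$data$config)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- payload$data
  restore_scaling <- function(s) {
    structure(list(center = unlist(s$center), scale = unlist(s$scale),
                   mode = s$mode), class = "qsrr_scaling")
  }
  switch(payload$class,
    qsrr_scaling = restore_scaling(d),
    qsrr_pls = {
      d$W <- as.matrix(d$W); d$P <- as.matrix(d$P)
      d$T <- as.matrix(d$T); d$U <- as.matrix(d$U)
      d$B <- matrix(unlist(d$B), ncol = 1L,
                    dimnames = list(d$var_names, NULL))
      rownames(d$W) <- rownames(d$P) <- d$var_names
      d$D <- as.matrix(d$D)
      d$x_scaling <- restore_scaling(d$x_scaling)
      d$y_scaling <- restore_scaling(d$y_scaling)
      structure(d, class = "qsrr_pls")
    },
    qsrr_ann = {
      d$w$W1 <- as.matrix(d$w$W1)
      d$w$w2 <- as.numeric(d$w$w2)
      d$w$b1 <- as.numeric(d$w$b1)
      d$w$b2 <- as.numeric(d$w$b2)
      d$x_scaling <- restore_scaling(d$x_scaling)
      d$config <- structure(d$config, class = "qsrr_ann_config")
      d$trace <- tibble::as_tibble(d$trace)
      structure(d, class = "qsrr_ann")
    },
    stop("read_model_json(): unknown class tag ", payload$class, call. = FALSE)
  )
}
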