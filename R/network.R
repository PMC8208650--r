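#' @keywords internal
#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @useDynLib thetagate, .registration = TRUE
"_PACKAGE"

new_network <- function(cells, edges, params, topology_seed = NA_integer_) {
  stopifnot(all(edges$weight >= 0), !any(edges$pre == edges$post))
  structure(list(
    n_stellate = sum(cells$type == "stellate"),
    n_interneuron = sum(cells$type == "interneuron"),
    cells = cells,
    edges = edges,
    params = params,
    topology_seed = topology_seed
  ), class = "mec_network")
}

#' @export
print.mec_network <- function(x, ...) {
  cat("<mec_network> ", x$n_stellate, " stellate + ", x$n_interneuron,
      " interneuron cells, ", nrow(x$edges), " synapses\n", sep = "")
  blk <- dplyr::count(x$edges, .data$block)
  for (i in seq_len(nrow(blk)))
    cat("  ", blk$block[i], ": ", blk$n[i], " edges\n", sep = "")
  invisible(x)
}

#' Bundle of cell and synapse parameters for a network
#'
#' @param stellate,interneuron Cell parameter objects.
#' @param syn_exc,syn_inh Synapse parameter objects.
#' @return Named list.
#' @export
default_net_params <- function(stellate = stellate_params(),
                               interneuron = interneuron_params(),
                               syn_exc = synapse_params("excitatory"),
                               syn_inh = synapse_params("inhibitory")) {
  list(stellate = stellate, interneuron = interneuron,
       syn_exc = syn_exc, syn_inh = syn_inh)
}

cells_table <- function(n_stellate, n_interneuron, drive_s, drive_i,
                        groups = NULL) {
  tibble::tibble(
    id = seq_len(n_stellate + n_interneuron),
    type = rep(c("stellate", "interneuron"), c(n_stellate, n_interneuron)),
    group = c(rep(NA_character_, n_stellate),
              groups %||% rep(NA_character_, n_interneuron)),
    drive = rep(c(drive_s, drive_i), c(n_stellate, n_interneuron)))
}

ii_all_to_all <- function(in_ids, gii) {
  g <- tidyr::expand_grid(pre = in_ids, post = in_ids)
  g <- dplyr::filter(g, .data$pre != .data$post)
  dplyr::mutate(g, block = "ii", weight = gii)
}

#' Two-cell motif network
#'
#' The elementary MEC motif: two stellate cells and two interneurons. The
#' interneurons inhibit each other and each inhibits its partner stellate
#' cell; each stellate cell excites the opposite interneuron, closing the
#' loop that makes the motif an autonomous oscillator. Removing the feedback
#' excitation freezes the motif into continuous firing of one interneuron.
#'
#' Cell ids: stellate 1, 2; interneurons 3, 4. Interneuron 3 inhibits
#' stellate 1 and stellate 1 excites interneuron 4 (and symmetrically).
#'
#' @param include_feedback_excitation Include the stellate-to-interneuron
#'   excitatory connections?
#' @param gii,gie,gei Synaptic conductances (mS/cm\eqn{^2}): mutual
#'   interneuron inhibition, interneuron-to-stellate inhibition,
#'   stellate-to-interneuron excitation. The motif uses a stronger single
#'   excitatory contact than the ring default so one rebound spike can recruit
#'   the opposite interneuron.
#' @param drive_s,drive_i Constant drives (\eqn{\mu}A/cm\eqn{^2}).
#' @param params Cell/synapse parameter set from [default_net_params()].
#' @return An `mec_network`.
#' @export
build_motif <- function(include_feedback_excitation = TRUE,
                        gii = 1.0, gie = 0.6, gei = 0.15,
                        drive_s = -2.7, drive_i = 0.2,
                        params = default_net_params()) {
  cells <- cells_table(2, 2, drive_s, drive_i)
  edges <- dplyr::bind_rows(
    tibble::tibble(pre = c(3L, 4L), post = c(1L, 2L), block = "ie", weight = gie),
    ii_all_to_all(c(3L, 4L), gii),
    if (include_feedback_excitation)
      tibble::tibble(pre = c(1L, 2L), post = c(4L, 3L), block = "ei",
                     weight = gei))
  new_network(cells, edges, params)
}

#' Isolated single-cell "network"
#'
#' One stellate cell or interneuron with a constant drive and no synapses;
#' used for single-cell characterisation (subthreshold oscillations, rebound
#' spiking, tonic firing).
#'
#' @param type `"stellate"` or `"interneuron"`.
#' @param drive Constant external current (\eqn{\mu}A/cm\eqn{^2}); defaults
#'   to the published value for the cell type.
#' @param params Cell/synapse parameters.
#' @return An `mec_network` with a single cell (id 1).
#' @export
build_isolated <- function(type = c("stellate", "interneuron"), drive = NULL,
                           params = default_net_params()) {
  type <- match.arg(type)
  drive <- drive %||% if (type == "stellate") -2.7 else 0.2
  cells <- tibble::tibble(id = 1L, type = type, group = NA_character_,
                          drive = drive)
  edges <- tibble::tibble(pre = integer(), post = integer(),
                          block = character(), weight = numeric())
  new_network(cells, edges, params)
}

#' Rebound probe: one interneuron inhibiting one stellate cell
#'
#' The interneuron is held silent by a hyperpolarizing drive and fired with a
#' brief strong pulse, delivering a single inhibitory spike to the stellate
#' cell so its rebound response can be observed.
#'
#' @param gie Inhibitory conductance onto the stellate cell (mS/cm\eqn{^2}).
#' @param drive_s Stellate drive.
#' @param drive_i Interneuron holding drive (subthreshold).
#' @param params Cell/synapse parameters.
#' @return An `mec_network`; stellate id 1, interneuron id 2.
#' @export
build_rebound_pair <- function(gie = 0.6, drive_s = -2.7, drive_i = -1,
                               params = default_net_params()) {
  cells <- cells_table(1, 1, drive_s, drive_i)
  edges <- tibble::tibble(pre = 2L, post = 1L, block = "ie", weight = gie)
  new_network(cells, edges, params)
}

ring_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

ie_gaussian_block <- function(in_ids, n, fanout, sigma, gie) {
  half <- (fanout - 1) %/% 2
  purrr::map(seq_along(in_ids), function(ii) {
    offs <- seq(-half, half)
    post <- ((ii - 1 + offs) %% n) + 1
    tibble::tibble(pre = in_ids[ii], post = as.integer(post), block = "ie",
                   weight = gie * exp(-offs^2 / (2 * sigma^2)))
  }) |> purrr::list_rbind()
}

#' Ring network of stellate cells and interneurons
#'
#' Stellate cells and interneurons arranged on parallel rings. Interneuron
#' `i` inhibits the `inhib_fanout` stellate cells centred on position `i`
#' (ring wrap-around) with a Gaussian weight profile peak-normalised at
#' `gie`; each stellate cell excites `excit_fanout` interneurons drawn
#' uniformly without replacement under `seed`; interneurons are all-to-all
#' inhibitory.
#'
#' @param n_stellate,n_interneuron Population sizes.
#' @param inhib_fanout Stellate cells contacted by each interneuron (odd).
#' @param excit_fanout Interneurons contacted by each stellate cell.
#' @param sigma Gaussian width of the inhibitory profile (index units).
#' @param gii,gie,gei Synaptic conductances (mS/cm\eqn{^2}).
#' @param drive_s,drive_i Constant drives (\eqn{\mu}A/cm\eqn{^2}).
#' @param seed Topology seed for the random excitatory feedback.
#' @param params Cell/synapse parameters.
#' @return An `mec_network`. Stellate ids `1..n_stellate`, interneuron ids
#'   follow.
#' @export
build_ring <- function(n_stellate = 40, n_interneuron = 40,
                       inhib_fanout = 5, excit_fanout = 6, sigma = 1.25,
                       gii = 1.0, gie = 0.6, gei = 0.03,
                       drive_s = -2.7, drive_i = 0.2,
                       seed = 1, params = default_net_params()) {
  if (inhib_fanout > n_stellate || excit_fanout > n_interneuron)
    stop("fan-out exceeds population size", call. = FALSE)
  ns <- n_stellate; ni <- n_interneuron
  in_ids <- ns + seq_len(ni)
  cells <- cells_table(ns, ni, drive_s, drive_i)
  ie <- ie_gaussian_block(in_ids, ns, inhib_fanout, sigma, gie)
  rng <- sample_rng(seed)
  ei <- purrr::map(seq_len(ns), function(s) {
    tgt <- rng$sample_no_replace(ni, excit_fanout)
    tibble::tibble(pre = s, post = ns + tgt, block = "ei", weight = gei)
  }) |> purrr::list_rbind()
  edges <- dplyr::bind_rows(ie, ei, ii_all_to_all(in_ids, gii))
  new_network(cells, edges, params, topology_seed = seed)
}

# small deterministic sampler independent of R's global RNG state
sample_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
  list(
    nxt_u = function() nxt(),
    sample_no_replace = function(n, k) {
      pool <- seq_len(n)
      out <- integer(k)
      for (j in seq_len(k)) {
        idx <- 1 + floor(nxt() * length(pool))
        idx <- min(idx, length(pool))
        out[j] <- pool[idx]
        pool <- pool[-idx]
      }
      as.integer(out)
    })
}

#' Ring network with asymmetric local feedback excitation
#'
#' As [build_ring()], but the stellate-to-interneuron excitation is local and
#' asymmetric instead of random: each stellate cell projects with a Gaussian
#' weight profile centred `offset` positions away from its own ring position,
#' with width `sigma_e`, total outgoing weight normalised to
#' `excit_fanout * gei` so the aggregate excitatory drive matches the
#' random-feedback regime.
#'
#' @inheritParams build_ring
#' @param offset Index shift of the excitatory profile centre.
#' @param sigma_e Gaussian width of the excitatory profile (index units).
#' @param window Half-width of the truncation window around the centre.
#' @return An `mec_network`.
#' @export
build_asymmetric_ring <- function(n_stellate = 40, n_interneuron = 40,
                                  inhib_fanout = 5, sigma = 1.25,
                                  offset = 2, sigma_e = 1.5, window = 3,
                                  excit_fanout = 6,
                                  gii = 1.0, gie = 0.6, gei = 0.03,
                                  drive_s = -2.7, drive_i = 0.2,
                                  params = default_net_params()) {
  if (abs(offset) >= n_interneuron / 2)
    stop("|offset| must be < n_interneuron / 2", call. = FALSE)
  ns <- n_stellate; ni <- n_interneuron
  in_ids <- ns + seq_len(ni)
  cells <- cells_table(ns, ni, drive_s, drive_i)
  ie <- ie_gaussian_block(in_ids, ns, inhib_fanout, sigma, gie)
  ei <- purrr::map(seq_len(ns), function(s) {
    offs <- seq(-window, window)
    w <- exp(-offs^2 / (2 * sigma_e^2))
    w <- w * (excit_fanout * gei) / sum(w)
    post <- ((s - 1 + offset + offs) %% ni) + 1
    tibble::tibble(pre = s, post = ns + as.integer(post), block = "ei",
                   weight = w)
  }) |> purrr::list_rbind()
  edges <- dplyr::bind_rows(ie, ei, ii_all_to_all(in_ids, gii))
  new_network(cells, edges, params)
}

#' Dual-ring network with two competing interneuron populations
#'
#' Two interneuron subpopulations (groups "A" and "B"), each wired to the
#' common stellate ring exactly as in [build_ring()]; all interneurons across
#' both groups are mutually inhibitory, so the two rings compete for control
#' of the shared stellate pool.
#'
#' @inheritParams build_ring
#' @param n_per_group Interneurons per subpopulation.
#' @return An `mec_network` with interneuron `group` labels "A" and "B".
#' @export
build_dual_ring <- function(n_stellate = 40, n_per_group = 40,
                            inhib_fanout = 5, excit_fanout = 6, sigma = 1.25,
                            gii = 1.0, gie = 0.6, gei = 0.03,
                            drive_s = -2.7, drive_i = 0.2,
                            seed = 1, params = default_net_params()) {
  ns <- n_stellate
  ni <- 2 * n_per_group
  cells <- cells_table(ns, ni, drive_s, drive_i,
                       groups = rep(c("A", "B"), each = n_per_group))
  ids_a <- ns + seq_len(n_per_group)
  ids_b <- ns + n_per_group + seq_len(n_per_group)
  ie <- dplyr::bind_rows(
    ie_gaussian_block(ids_a, ns, inhib_fanout, sigma, gie),
    ie_gaussian_block(ids_b, ns, inhib_fanout, sigma, gie))
  rng <- sample_rng(seed)
  ei <- purrr::map(seq_len(ns), function(s) {
    tgt <- rng$sample_no_replace(ni, excit_fanout)
    tibble::tibble(pre = s, post = ns + tgt, block = "ei", weight = gei)
  }) |> purrr::list_rbind()
  edges <- dplyr::bind_rows(ie, ei, ii_all_to_all(ns + seq_len(ni), gii))
  new_network(cells, edges, params, topology_seed = seed)
}

#' Edge list of a network
#'
#' @param net An `mec_network`.
#' @return Tibble with columns `pre`, `post`, `block`, `weight`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "mec_network"))
  net$edges
}

#' Write / read a network edge list as plain text
#'
#' Tab-separated columns `pre`, `post`, `block`, `weight`.
#'
#' @param net An `mec_network`.
#' @param path File path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns the edge tibble.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(network_edges(net), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
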