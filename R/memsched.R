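## Compute-graph memory scheduler: Group Execution and Group Prefetch.
##
## Unified-memory training swaps intermediate tensors between accelerator and
## host memory. Grouping consecutive operations so each group's intermediate
## data fits the memory budget curbs thrashing (Group Execution); issuing an
## explicit copy of the next group's data while the current group computes
## hides transfer latency (Group Prefetch). Times here are simulated from
## configurable transfer rates, never measured.

#' Build an operation graph
#'
#' @param nodes list of nodes, each `list(id =, deps = character vector,
#'   bytes = intermediate data size)`. Must form a DAG.
#' @return an `op_graph`.
#' @export
op_graph <- function(nodes) {
  ids <- vapply(nodes, `[[`, character(1), "id")
  stopifnot(!anyDuplicated(ids))
  for (n in nodes)
    if (!all(n$deps %in% ids))
      stop("unknown dependency in node ", n$id)
  structure(list(nodes = nodes, ids = ids), class = "op_graph")
}

#' Read / write the JSON node-list dialect
#' @param path JSON file with an array of `{id, deps, bytes}` objects.
#' @return an [op_graph()].
#' @export
read_op_graph <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  op_graph(lapply(raw, function(n)
    list(id = n$id, deps = as.character(unlist(n$deps)),
         bytes = as.numeric(n$bytes))))
}

#' @rdname read_op_graph
#' @param graph an [op_graph()].
#' @export
write_op_graph <- function(graph, path) {
  out <- lapply(graph$nodes, function(n)
    list(id = n$id, deps = I(as.character(n$deps)), bytes = n$bytes))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Topological sort with deterministic tie-breaking
#'
#' Kahn's algorithm; among ready operations the lexicographically smallest id
#' runs first, so the sequence is unique. A cycle raises an error naming one
#' of its edges.
#'
#' @param graph an [op_graph()].
#' @return character vector of op ids, every op after its dependencies.
#' @export
toposort <- function(graph) {
  stopifnot(inherits(graph, "op_graph"))
  deps <- lapply(graph$nodes, `[[`, "deps")
  names(deps) <- graph$ids
  remaining <- graph$ids
  out <- character(0)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(deps[remaining],
                              function(d) all(d %in% out), logical(1))]
    if (length(ready) == 0) {
      v <- remaining[1]
      u <- setdiff(deps[[v]], out)[1]
      stop(sprintf("cycle detected involving edge %s -> %s", u, v))
    }
    nxt <- sort(ready)[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' Plan memory-bounded execution groups
#'
#' Walks the topologically sorted sequence and makes each group the longest
#' prefix of the remaining operations whose total intermediate bytes stay
#' within the budget. An operation that alone exceeds the budget becomes a
#' singleton overflow group, with a warning.
#'
#' @param graph an [op_graph()].
#' @param budget_bytes memory budget per group (> 0).
#' @return a `group_plan`: list with `groups` (list of id vectors),
#'   `group_bytes`, `budget_bytes`, `sequence`, and empty control/prefetch
#'   slots (see [add_control_and_prefetch()]).
#' @export
plan_groups <- function(graph, budget_bytes) {
  stopifnot(budget_bytes > 0)
  seqs <- toposort(graph)
  bytes <- vapply(graph$nodes, `[[`, numeric(1), "bytes")
  names(bytes) <- graph$ids
  groups <- list()
  cur <- character(0); cur_bytes <- 0
  for (id in seqs) {
    b <- bytes[[id]]
    if (b > budget_bytes && length(cur) == 0) {
      warning(sprintf("operation %s (%g bytes) exceeds the budget alone", id, b))
      groups[[length(groups) + 1L]] <- id
      next
    }
    if (cur_bytes + b > budget_bytes && length(cur) > 0) {
      groups[[length(groups) + 1L]] <- cur
      cur <- character(0); cur_bytes <- 0
      if (b > budget_bytes) {
        warning(sprintf("operation %s (%g bytes) exceeds the budget alone", id, b))
        groups[[length(groups) + 1L]] <- id
        next
      }
    }
    cur <- c(cur, id); cur_bytes <- cur_bytes + b
  }
  if (length(cur) > 0) groups[[length(groups) + 1L]] <- cur
  structure(list(groups = groups,
                 group_bytes = vapply(groups, function(g) sum(bytes[g]),
                                      numeric(1)),
                 budget_bytes = budget_bytes, sequence = seqs,
                 control_deps = NULL, prefetch_ops = NULL),
            class = "group_plan")
}

#' Add control dependencies and prefetch operations to a plan
#'
#' Inserts a control edge from each group to its successor (forcing
#' sequential group execution) and one prefetch op per group beyond the
#' first, issued during the preceding group and covering the group's input
#' bytes.
#'
#' @param plan a [plan_groups()] result.
#' @return the plan with `control_deps` (data.frame from, to) and
#'   `prefetch_ops` (data.frame target_group, issued_during, bytes).
#' @export
add_control_and_prefetch <- function(plan) {
  stopifnot(inherits(plan, "group_plan"))
  g <- length(plan$groups)
  plan$control_deps <- if (g > 1)
    data.frame(from = seq_len(g - 1), to = seq_len(g - 1) + 1)
  else
    data.frame(from = integer(0), to = integer(0))
  plan$prefetch_ops <- if (g > 1)
    data.frame(target_group = 2:g, issued_during = 1:(g - 1),
               bytes = plan$group_bytes[2:g])
  else
    data.frame(target_group = integer(0), issued_during = integer(0),
               bytes = numeric(0))
  plan
}

#' Serialize / restore a group plan as JSON
#'
#' @param plan a `group_plan`.
#' @param path JSON file path.
#' @return `write_group_plan` the path; `read_group_plan` the plan.
#' @export
write_group_plan <- function(plan, path) {
  out <- list(groups = plan$groups, group_bytes = plan$group_bytes,
              budget_bytes = plan$budget_bytes, sequence = plan$sequence,
              control_deps = plan$control_deps,
              prefetch_ops = plan$prefetch_ops)
  writeLines(jsonlite::toJSON(out, auto_unbox = FALSE, digits = NA), path)
  invisible(path)
}

#' @rdname write_group_plan
#' @export
read_group_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_df <- function(x) if (length(x) == 0) NULL else
    do.call(rbind, lapply(x, function(row) as.data.frame(row)))
  structure(list(groups = lapply(raw$groups, function(g)
                   as.character(unlist(g))),
                 group_bytes = as.numeric(unlist(raw$group_bytes)),
                 budget_bytes = as.numeric(raw$budget_bytes[[1]]),
                 sequence = as.character(unlist(raw$sequence)),
                 control_deps = as_df(raw$control_deps),
                 prefetch_ops = as_df(raw$prefetch_ops)),
            class = "group_plan")
}

#' Swap-model parameters
#'
#' Default rates follow the measured unified-memory transfer asymmetry:
#' on-demand page migration at 3.6 GB/s versus explicit copy at 10.3 GB/s.
#'
#' @param ondemand_rate bytes/second for on-demand access.
#' @param explicit_rate bytes/second for explicit prefetch copies.
#' @return a `swap_model`.
#' @export
swap_model <- function(ondemand_rate = 3.6e9, explicit_rate = 10.3e9) {
  stopifnot(ondemand_rate > 0, explicit_rate > 0)
  structure(list(ondemand_rate = ondemand_rate, explicit_rate = explicit_rate),
            class = "swap_model")
}

#' Simulate transfer/compute time of a plan
#'
#' On-demand mode: every group's bytes migrate at the on-demand rate,
#' serialized with its compute. Prefetch mode: the first group's bytes load
#' up-front at the explicit-copy rate, and each subsequent group's transfer
#' overlaps the previous group's compute (per-slot time is the max of the
#' two); transfers run at the explicit rate. Whenever the explicit rate is at
#' least the on-demand rate, the prefetch-mode total never exceeds the
#' on-demand total.
#'
#' @param plan a [group_plan] (prefetch ops optional).
#' @param swap a [swap_model()].
#' @param compute_time_per_group numeric vector, seconds per group.
#' @return list with `ondemand` and `prefetch`, each `(total_time,
#'   bytes_moved)`.
#' @export
simulate_transfer <- function(plan, swap, compute_time_per_group) {
  stopifnot(inherits(plan, "group_plan"), inherits(swap, "swap_model"))
  g <- length(plan$groups)
  ct <- rep_len(compute_time_per_group, g)
  b <- plan$group_bytes
  ondemand <- sum(ct) + sum(b) / swap$ondemand_rate
  pre <- b[1] / swap$explicit_rate
  for (i in seq_len(g)) {
    nxt <- if (i < g) b[i + 1] / swap$explicit_rate else 0
    pre <- pre + max(ct[i], nxt)
  }
  list(ondemand = list(total_time = ondemand, bytes_moved = sum(b)),
       prefetch = list(total_time = pre, bytes_moved = sum(b)))
}

#' Random operation DAG (for property testing and examples)
#'
#' Each op depends on a random subset of earlier ops, so the graph is acyclic
#' by construction.
#'
#' @param n_ops number of operations.
#' @param seed seed.
#' @param max_bytes upper bound for per-op intermediate bytes.
#' @return an [op_graph()].
#' @export
random_op_graph <- function(n_ops, seed = 1L, max_bytes = 10) {
  with_seed(seed, {
    nodes <- vector("list", n_ops)
    ids <- sprintf("op%03d", seq_len(n_ops))
    for (i in seq_len(n_ops)) {
      deps <- if (i > 1 && runif(1) < 0.7)
        sample(ids[seq_len(i - 1)], sample.int(min(3, i - 1), 1))
      else character(0)
      nodes[[i]] <- list(id = ids[i], deps = deps,
                         bytes = sample.int(max_bytes, 1))
    }
    op_graph(nodes)
  })
}
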