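#!/usr/bin/env python
"""Minimal single-resolution cooler (HDF5) reader/writer.

Implements the public cooler schema (format-version 3: chroms, bins,
pixels with upper-triangle storage, indexes/chrom_offset + bin1_offset)
so files interoperate with standard cooler tooling. Used by the R package
through the command line; communicates matrices as dense TSV.

Commands:
  create <path> <chrom> <start> <end> <resolution> <chrom_length>
         --matrix M.tsv [--weights w.txt]
  dump   <path> <chrom> <start> <end> <resolution> [--balance] --out out.tsv
"""

import argparse
import sys

import h5py
import numpy as np


def _read_dense(path):
    m = np.loadtxt(path, ndmin=2)
    if m.shape[0] != m.shape[1]:
        sys.exit("matrix is not square: %r" % (m.shape,))
    return m


def create(args):
    mat = _read_dense(args.matrix)
    n = mat.shape[0]
    res = args.resolution
    if args.end - args.start != n * res:
        sys.exit("region size does not match matrix dimension")
    clen = max(args.chrom_length, args.end)
    nbins_total = int(np.ceil(clen / res))
    starts = np.arange(nbins_total, dtype=np.int64) * res
    ends = np.minimum(starts + res, clen)
    off = args.start // res  # first region bin id

    weights = None
    if args.weights:
        weights = np.loadtxt(args.weights, ndmin=1)
        if weights.size != n:
            sys.exit("weights length != matrix dimension")

    # upper-triangle pixels of the region block, global bin ids
    iu = np.triu_indices(n)
    counts = mat[iu]
    keep = np.isfinite(counts) & (counts != 0)
    bin1 = iu[0][keep] + off
    bin2 = iu[1][keep] + off
    counts = counts[keep]
    order = np.lexsort((bin2, bin1))
    bin1, bin2, counts = bin1[order], bin2[order], counts[order]

    bin1_offset = np.zeros(nbins_total + 1, dtype=np.int64)
    cnt = np.bincount(bin1, minlength=nbins_total)
    bin1_offset[1:] = np.cumsum(cnt)

    with h5py.File(args.path, "w") as f:
        f.attrs["format"] = "HDF5::Cooler"
        f.attrs["format-version"] = 3
        f.attrs["bin-type"] = "fixed"
        f.attrs["bin-size"] = res
        f.attrs["nchroms"] = 1
        f.attrs["nbins"] = nbins_total
        f.attrs["nnz"] = int(counts.size)
        f.attrs["storage-mode"] = "symmetric-upper"
        g = f.create_group("chroms")
        g.create_dataset("name", data=np.array([args.chrom.encode()]),
                         dtype="S32")
        g.create_dataset("length", data=np.array([clen], dtype=np.int32))
        g = f.create_group("bins")
        g.create_dataset("chrom", data=np.zeros(nbins_total, dtype=np.int32))
        g.create_dataset("start", data=starts.astype(np.int32))
        g.create_dataset("end", data=ends.astype(np.int32))
        if weights is not None:
            w = np.full(nbins_total, np.nan)
            w[off:off + n] = weights
            g.create_dataset("weight", data=w)
        g = f.create_group("pixels")
        g.create_dataset("bin1_id", data=bin1)
        g.create_dataset("bin2_id", data=bin2)
        g.create_dataset("count", data=counts.astype(np.float64))
        g = f.create_group("indexes")
        g.create_dataset("chrom_offset",
                         data=np.array([0, nbins_total], dtype=np.int64))
        g.create_dataset("bin1_offset", data=bin1_offset)


def dump(args):
    with h5py.File(args.path, "r") as f:
        res = int(f.attrs["bin-size"])
        if res != args.resolution:
            sys.exit("resolution %d not stored (file has %d)"
                     % (args.resolution, res))
        names = [n.decode() if isinstance(n, bytes) else str(n)
                 for n in f["chroms/name"][:]]
        if args.chrom not in names:
            sys.exit("unknown chromosome %r" % args.chrom)
        ci = names.index(args.chrom)
        chrom_offset = f["indexes/chrom_offset"][:]
        lo_bin = int(chrom_offset[ci]) + args.start // res
        n = (args.end - args.start) // res
        hi_bin = lo_bin + n
        bin1_offset = f["indexes/bin1_offset"][:]
        p0, p1 = int(bin1_offset[lo_bin]), int(bin1_offset[hi_bin])
        mat = np.zeros((n, n))
        if p1 > p0:
            b1 = f["pixels/bin1_id"][p0:p1] - lo_bin
            b2 = f["pixels/bin2_id"][p0:p1] - lo_bin
            ct = f["pixels/count"][p0:p1].astype(float)
            keep = (b2 >= 0) & (b2 < n)
            b1, b2, ct = b1[keep], b2[keep], ct[keep]
            mat[b1, b2] = ct
            mat[b2, b1] = ct
        if args.balance:
            if "weight" not in f["bins"]:
                sys.exit("no balancing weights stored")
            w = f["bins/weight"][lo_bin:hi_bin]
            mat = mat * np.outer(w, w)
    np.savetxt(args.out, mat, fmt="%.17g")


def main(argv=None):
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)
    c = sub.add_parser("create")
    c.add_argument("path")
    c.add_argument("chrom")
    c.add_argument("start", type=int)
    c.add_argument("end", type=int)
    c.add_argument("resolution", type=int)
    c.add_argument("chrom_length", type=int)
    c.add_argument("--matrix", required=True)
    c.add_argument("--weights")
    d = sub.add_parser("dump")
    d.add_argument("path")
    d.add_argument("chrom")
    d.add_argument("start", type=int)
    d.add_argument("end", type=int)
    d.add_argument("resolution", type=int)
    d.add_argument("--balance", action="store_true")
    d.add_argument("--out", required=True)
    args = ap.parse_args(argv)
    if args.cmd == "create":
        create(args)
    else:
        dump(args)


if __name__ == "__main__":
    main()
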