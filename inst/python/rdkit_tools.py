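"""Batched RDKit helper for the squarescheme R package.

Called as:  python rdkit_tools.py MODE IN_CSV OUT_CSV [NBITS RADIUS CHIRAL]

MODE 'canon': IN_CSV has a 'smiles' column; writes row,ok,canonical,error.
MODE 'fp':    additionally takes NBITS RADIUS CHIRAL(0/1); writes
              row,ok,bits,error with 'bits' a 0/1 string of length NBITS.

Per-row failures are reported in the output, never fatal; the exit code
is non-zero only for usage or I/O errors.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main(argv):
    if len(argv) < 4:
        sys.stderr.write("usage: rdkit_tools.py MODE IN_CSV OUT_CSV [NBITS RADIUS CHIRAL]\n")
        return 2
    mode, in_csv, out_csv = argv[1], argv[2], argv[3]
    if mode not in ("canon", "fp"):
        sys.stderr.write("unknown mode: %s\n" % mode)
        return 2
    if mode == "fp":
        nbits, radius, chiral = int(argv[4]), int(argv[5]), argv[6] not in ("0", "FALSE")
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=radius, fpSize=nbits, includeChirality=chiral)

    with open(in_csv, newline="") as fin, open(out_csv, "w", newline="") as fout:
        reader = csv.DictReader(fin)
        writer = csv.writer(fout)
        writer.writerow(["row", "ok", "canonical" if mode == "canon" else "bits", "error"])
        for i, rec in enumerate(reader, start=1):
            smi = rec.get("smiles", "")
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                writer.writerow([i, 0, "", "unparsable SMILES: %r" % smi])
                continue
            if mode == "canon":
                writer.writerow([i, 1, Chem.MolToSmiles(mol), ""])
            else:
                fp = gen.GetFingerprint(mol)
                writer.writerow([i, 1, fp.ToBitString(), ""])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
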