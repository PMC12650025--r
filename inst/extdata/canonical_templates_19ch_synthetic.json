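{"description":"Synthetic idealized canonical microstate reference maps (A-D) on the 19-channel 10-20 montage; geometric approximations from electrode coordinates, not empirical grand averages.","channels":["Fp1","Fp2","F7","F3","Fz","F4","F8","T3","C3","Cz","C4","T4","T5","P3","Pz","P4","T6","O1","O2"],"templates":{"A":[0.0931196240045576,0.306550702874588,-0.154729223097271,-0.00823368122352467,0.105176401810301,0.239621765206188,0.402945531369582,-0.344243675596823,-0.15490965401857,0,0.15490965401857,0.344243675596823,-0.402945531369582,-0.239621765206188,-0.105176401810301,0.00823368122352467,0.154729223097271,-0.306550702874588,-0.0931196240045576],"B":[0.306550702874588,0.0931196240045576,0.402945531369582,0.239621765206188,0.105176401810301,-0.00823368122352467,-0.154729223097271,0.344243675596823,0.15490965401857,0,-0.15490965401857,-0.344243675596823,0.154729223097271,0.00823368122352467,-0.105176401810301,-0.239621765206188,-0.402945531369582,-0.0931196240045576,-0.306550702874588],"C":[-0.208114829839103,-0.208114829839103,-0.20447358911855,-0.183054733458052,-0.161001121291117,-0.183054733458052,-0.20447358911855,-0.180405228715218,0.00932280739088949,0.154077890434976,0.00932280739088949,-0.180405228715218,-0.0603762932806011,0.35111333986073,0.561106481412695,0.35111333986073,-0.0603762932806011,0.198896901881628,0.198896901881628],"D":[-0.0534322804284646,-0.0534322804284646,-0.124468029885928,0.259397246887222,0.705873260178029,0.259397246887222,-0.124468029885928,-0.148019837274763,0.0374108200807556,0.368513795422283,0.0374108200807556,-0.148019837274763,-0.151088688141378,-0.142779531118336,-0.125632674714944,-0.142779531118336,-0.151088688141378,-0.151396890561792,-0.151396890561792]}}
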