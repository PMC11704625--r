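Olivia
Liam
Emma
Noah
Amelia
Oliver
Sophia
Elijah
Charlotte
James
Ava
William
Isabella
Benjamin
Mia
Lucas
Evelyn
Henry
Harper
Theodore
Luna
Jack
Camila
Levi
Gianna
Alexander
Elizabeth
Jackson
Eleanor
Mateo
Ella
Daniel
Abigail
Michael
Sofia
Mason
Avery
Sebastian
Scarlett
Ethan
Emily
Logan
Aria
Owen
Penelope
Samuel
Chloe
Jacob
Layla
Asher
Mila
Aiden
Nora
John
Hazel
Joseph
Madison
Wyatt
Ellie
David
Lily
Leo
Nova
Luke
Isla
Julian
Grace
Hudson
Violet
Grayson
Aurora
Matthew
Riley
Ezra
Zoey
Gabriel
Willow
Carter
Emilia
Isaac
Stella
Jayden
Zoe
Luca
Victoria
Anthony
Hannah
Dylan
Addison
Lincoln
Leah
Thomas
Lucy
Maverick
Eliana
Elias
Ivy
Josiah
Everly
Charles
Lillian
Caleb
Paisley
Christopher
Elena
Ezekiel
Naomi
Miles
Maya
Jaxon
Natalie
Isaiah
Kinsley
Andrew
Delilah
Joshua
Claire
Nathan
Audrey
Nolan
Aaliyah
Adrian
Ruby
Cameron
Brooklyn
Santiago
Alice
Eli
Aubrey
Aaron
Autumn
Ryan
Leilani
Angel
Savannah
Cooper
Valentina
Waylon
Kennedy
Easton
Madelyn
Kai
Josephine
Christian
Bella
Landon
Skylar
Colton
Genesis
Roman
Sophie
Axel
Allison
Brooks
Gabriella
Jonathan
Serenity
Robert
Samantha
Jameson
Sarah
Ian
Quinn
Everett
Eva
Greyson
Piper
Wesley
Sloan
Jeremiah
Caroline
Hunter
Brielle
Leonardo
Jordan
Peyton
Jose
Athena
Bennett
Jade
Silas
Maria
Nicholas
Amara
Parker
Teagan
Beau
Arya
Weston
Eden
Austin
Anna
Connor
Iris
Carson
Jasmine
Dominic
Kayla
Xavier
Margaret
Jaxson
Juniper
Jace
Rowan
Emmett
Adeline
Adam
Melody
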